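#' Instrument definitions
#'
#' Returns the definition of one of the four instruments handled by the
#' package: the ICD-11-aligned International Depression Questionnaire (IDQ,
#' nine items) and International Anxiety Questionnaire (IAQ, eight items),
#' and the DSM-IV-aligned comparators PHQ-9 and GAD-7.
#'
#' IDQ and IAQ items are answered on a five-point frequency scale
#' (0 Never, 1 Only a few days, 2 Half the days, 3 Most days, 4 Every day).
#' An item is *endorsed* when the response is 3 or 4.  The diagnostic
#' algorithms combine three requirements: at least one endorsed core item
#' (items 1-2, the affective cluster / essential features), a minimum total
#' number of endorsed items (five for the IDQ, four for the IAQ), and a
#' "Yes" on the functional-impairment question.  PHQ-9 and GAD-7 are
#' scored 0-3 per item with screening caseness at a sum score of 10 or
#' more.
#'
#' @param name One of `"IDQ"`, `"IAQ"`, `"PHQ9"`, `"GAD7"`
#'   (case-insensitive; `"PHQ-9"`/`"GAD-7"` also accepted).
#' @return An object of class `instrument_spec`: a list with elements
#'   `name`, `abbreviation`, `n_items`, `item_texts` (NULL for the
#'   comparators), `max_response`, `score_max`, and, for the diagnostic
#'   instruments, `core_items`, `min_endorsed`, `endorsement_threshold`,
#'   `impairment_item`; for the comparators, `cutoff`.
#' @examples
#' idq <- instrument("IDQ")
#' idq$min_endorsed  # 5
#' @export
instrument <- function(name) {
  key <- tolower(gsub("-", "", name))
  defs <- instrument_definitions()
  if (!key %in% names(defs)) {
    stop("unknown instrument '", name, "'; available: IDQ, IAQ, PHQ9, GAD7")
  }
  d <- defs[[key]]
  diagnostic <- !is.null(d$items)
  spec <- list(
    name = d$name,
    abbreviation = d$abbreviation,
    n_items = if (diagnostic) length(d$items) else d$n_items,
    item_texts = d$items,
    max_response = d$max_response,
    anchors = d$anchors,
    diagnostic = diagnostic
  )
  spec$score_max <- spec$n_items * spec$max_response
  if (diagnostic) {
    spec$core_items <- as.integer(d$core_items)
    spec$min_endorsed <- as.integer(d$min_endorsed)
    spec$endorsement_threshold <- as.integer(d$endorsement_threshold)
    spec$impairment_item <- d$impairment_item
    spec$timeframe <- d$timeframe
    stopifnot(
      all(spec$core_items >= 1), all(spec$core_items <= spec$n_items),
      spec$min_endorsed <= spec$n_items
    )
  } else {
    spec$cutoff <- as.integer(d$cutoff)
  }
  class(spec) <- "instrument_spec"
  spec
}

# yaml resource cached per session
instrument_definitions <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "instruments.yaml", package = "idqiaq")
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' @export
print.instrument_spec <- function(x, ...) {
  cat(x$name, " (", x$abbreviation, "): ", x$n_items, " items, scored 0-",
      x$max_response, " (range 0-", x$score_max, ")\n", sep = "")
  if (isTRUE(x$diagnostic)) {
    cat("Diagnostic rule: core item ", paste(x$core_items, collapse = " or "),
        " endorsed, >=", x$min_endorsed,
        " items endorsed (response >= ", x$endorsement_threshold,
        "), impairment = yes\n", sep = "")
  } else {
    cat("Screening caseness: sum score >=", x$cutoff, "\n")
  }
  invisible(x)
}

check_responses <- function(values, spec, what = "response") {
  values <- as.vector(values, mode = "numeric")
  if (length(values) != spec$n_items) {
    stop(spec$abbreviation, " expects ", spec$n_items, " item responses, got ",
         length(values))
  }
  if (anyNA(values)) {
    stop(spec$abbreviation, " responses contain missing values (items ",
         paste(which(is.na(values)), collapse = ", "),
         "); complete cases are required for scoring")
  }
  bad <- which(values < 0 | values > spec$max_response | values != floor(values))
  if (length(bad)) {
    stop("invalid ", what, " for ", spec$abbreviation, " item",
         if (length(bad) > 1) "s", " ",
         paste(bad, collapse = ", "), ": values must be integers in 0-",
         spec$max_response)
  }
  as.integer(values)
}

#' Item endorsement indicator
#'
#' Dichotomizes one respondent's ordinal item responses at the instrument's
#' endorsement threshold: an item is endorsed when the response is
#' "Most days" (3) or "Every day" (4).
#'
#' @param values Integer vector of item responses, one per item, each in
#'   0-4.
#' @param spec An [instrument()] definition (IDQ or IAQ).
#' @return Logical vector of length `spec$n_items`.
#' @examples
#' endorsements(c(0, 1, 2, 3, 4, 0, 0, 0, 0), instrument("IDQ"))
#' @export
endorsements <- function(values, spec) {
  stopifnot(inherits(spec, "instrument_spec"), isTRUE(spec$diagnostic))
  values <- check_responses(values, spec)
  values >= spec$endorsement_threshold
}

#' Severity sum score
#'
#' The severity score is the plain sum of the item responses, giving a
#' range of 0-36 for the IDQ and 0-32 for the IAQ.  No severity cut-off is
#' defined for either instrument; caseness comes from the diagnostic
#' algorithm instead.
#'
#' @inheritParams endorsements
#' @param spec An [instrument()] definition.
#' @return Integer sum score.
#' @export
sum_score <- function(values, spec) {
  values <- check_responses(values, spec)
  sum(values)
}

#' Apply a diagnostic algorithm
#'
#' Applies the ICD-11-derived diagnostic rule of the IDQ or IAQ to one
#' respondent: caseness requires (i) at least one endorsed core item
#' (items 1 or 2), (ii) at least `min_endorsed` endorsed items in total
#' (five for the IDQ, four for the IAQ), and (iii) a "yes" on the
#' functional-impairment question.
#'
#' When the impairment answer is missing but the symptom requirements are
#' met, caseness cannot be determined and `case` is `NA`; when the symptom
#' requirements fail, the respondent is a non-case regardless of the
#' impairment answer.
#'
#' @inheritParams endorsements
#' @param impairment Logical (or `"yes"`/`"no"`): answer to the
#'   functional-impairment question; may be `NA`.
#' @return An object of class `diagnostic_result`: list with
#'   `endorsed_mask`, `n_endorsed`, `core_met`, `impairment_met`, `case`
#'   (logical, `NA` if undetermined), and `sum_score`.
#' @examples
#' diagnose(c(3, 0, 3, 3, 3, 3, 0, 0, 0), TRUE, instrument("IDQ"))$case
#' @export
diagnose <- function(values, impairment, spec) {
  stopifnot(inherits(spec, "instrument_spec"), isTRUE(spec$diagnostic))
  if (is.character(impairment)) {
    impairment <- switch(tolower(impairment), yes = TRUE, no = FALSE,
                         as.logical(NA))
  }
  impairment <- as.logical(impairment)
  stopifnot(length(impairment) == 1L)
  mask <- endorsements(values, spec)
  n_end <- sum(mask)
  core <- any(mask[spec$core_items])
  symptoms_met <- core && n_end >= spec$min_endorsed
  case <- if (!symptoms_met) FALSE else if (is.na(impairment)) NA else impairment
  structure(list(
    instrument = spec$abbreviation,
    endorsed_mask = mask,
    n_endorsed = n_end,
    core_met = core,
    impairment_met = impairment,
    case = case,
    sum_score = sum_score(values, spec)
  ), class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(x$instrument, "diagnosis: ",
      if (is.na(x$case)) "undetermined (impairment missing)"
      else if (x$case) "CASE" else "non-case", "\n")
  cat("  endorsed:", x$n_endorsed, "items; core item endorsed:",
      x$core_met, "; impairment:", x$impairment_met,
      "; sum score:", x$sum_score, "\n")
  invisible(x)
}

#' PHQ-9 / GAD-7 comparator scoring
#'
#' Sums 0-3 item responses and applies the conventional screening cut-off
#' (score of 10 or more) to flag possible caseness.
#'
#' @param values Integer vector of item responses in 0-3 (nine for the
#'   PHQ-9, seven for the GAD-7).
#' @param spec An [instrument()] definition (`"PHQ9"` or `"GAD7"`).
#' @param cutoff Screening cut-off; defaults to the instrument's standard
#'   value (10).
#' @return List with `score` (integer) and `case` (logical).
#' @examples
#' comparator_case(rep(3, 7), instrument("GAD7"))  # score 21, case TRUE
#' @export
comparator_case <- function(values, spec, cutoff = spec$cutoff) {
  stopifnot(inherits(spec, "instrument_spec"), !isTRUE(spec$diagnostic))
  values <- check_responses(values, spec)
  score <- sum(values)
  list(score = score, case = score >= cutoff)
}

#' Prevalence with Wilson score interval
#'
#' Point prevalence `n_cases / n_total` with a Wilson score confidence
#' interval (the interval obtained by inverting the normal-approximation
#' score test, computed via [stats::prop.test()] without continuity
#' correction).
#'
#' @param n_cases,n_total Case count and sample size (`n_total >= 1`).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `prevalence_result`: list with `n_cases`,
#'   `n_total`, `proportion`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' prevalence_ci(152, 2058)  # 7.4% (6.3%, 8.6%)
#' @export
prevalence_ci <- function(n_cases, n_total, conf_level = 0.95) {
  stopifnot(length(n_cases) == 1L, length(n_total) == 1L)
  if (n_total < 1) stop("n_total must be at least 1")
  if (n_cases < 0 || n_cases > n_total) stop("need 0 <= n_cases <= n_total")
  ci <- stats::prop.test(n_cases, n_total, conf.level = conf_level,
                         correct = FALSE)$conf.int
  structure(list(
    n_cases = as.integer(n_cases), n_total = as.integer(n_total),
    proportion = n_cases / n_total,
    ci_low = ci[1], ci_high = ci[2], conf_level = conf_level
  ), class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, digits = 1, ...) {
  cat(sprintf("%.*f%% (%d/%d; %g%% CI %.*f%%, %.*f%%)\n",
              digits, 100 * x$proportion, x$n_cases, x$n_total,
              100 * x$conf_level, digits, 100 * x$ci_low,
              digits, 100 * x$ci_high))
  invisible(x)
}
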