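# Analysis pipeline: validated cohort I/O, the full validation analysis
# (item distributions, reliability, IRT, model comparison, prevalence and
# criterion associations), and deterministic report output.

cohort_columns <- function() {
  c("respondent_id", paste0("idq", 1:9), "idq_impair",
    paste0("iaq", 1:8), "iaq_impair", paste0("phq", 1:9),
    paste0("gad", 1:7), "sex", "age", "treatment_status")
}

#' Read and validate a cohort CSV
#'
#' Reads a respondent-level table in the cohort schema (IDQ/IAQ 0-4
#' items, yes/no impairment answers, PHQ-9/GAD-7 0-3 items, sex, age,
#' treatment status).  Column names must match the schema exactly (order
#' free); unknown or missing columns are an error naming the offenders.
#' Out-of-range item values are set to missing with a warning and counted
#' — under the complete-case policy such respondents drop out of the
#' affected scale's analyses only.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `cohort_table`; attribute
#'   `"validation_log"` records the counts of invalidated values.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty cohort file: ", path)
  validate_cohort(tab)
}

#' @rdname read_cohort
#' @param tab A data frame already in memory.
#' @export
validate_cohort <- function(tab) {
  want <- cohort_columns()
  unknown <- setdiff(names(tab), want)
  missing <- setdiff(want, names(tab))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[, want]
  if (anyDuplicated(tab$respondent_id)) stop("duplicated respondent_id")
  log <- character()
  clamp <- function(cols, lo, hi, label) {
    bad_total <- 0L
    for (cc in cols) {
      v <- suppressWarnings(as.numeric(tab[[cc]]))
      bad <- !is.na(v) & (v < lo | v > hi | v != floor(v))
      bad_total <- bad_total + sum(bad)
      v[bad] <- NA
      tab[[cc]] <<- as.integer(v)
    }
    if (bad_total > 0) {
      msg <- paste0(bad_total, " out-of-range ", label,
                    " value(s) set to missing")
      warning(msg)
      log <<- c(log, msg)
    }
  }
  clamp(paste0("idq", 1:9), 0, 4, "IDQ")
  clamp(paste0("iaq", 1:8), 0, 4, "IAQ")
  clamp(paste0("phq", 1:9), 0, 3, "PHQ-9")
  clamp(paste0("gad", 1:7), 0, 3, "GAD-7")
  for (cc in c("idq_impair", "iaq_impair")) {
    v <- tolower(as.character(tab[[cc]]))
    v[!v %in% c("yes", "no")] <- NA
    tab[[cc]] <- v
  }
  attr(tab, "validation_log") <- log
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Apply a diagnostic algorithm to a whole cohort
#'
#' Vectorized version of [diagnose()]: dichotomizes the instrument's item
#' columns at the endorsement threshold and applies the core-item,
#' symptom-count and impairment rules row by row.  Respondents with any
#' missing item response are excluded from that scale (complete-case per
#' scale): their `case` is `NA` and `valid` is `FALSE`.  Respondents with
#' complete symptoms meeting the symptom rule but a missing impairment
#' answer get `case = NA` with `valid = TRUE` (undetermined, reported
#' separately).
#'
#' @param cohort A `cohort_table`.
#' @param spec [instrument()] definition (IDQ or IAQ).
#' @return Data frame with `respondent_id`, `valid`, `sum_score`,
#'   `n_endorsed`, `core_met`, `impairment`, `case`.
#' @export
diagnose_cohort <- function(cohort, spec) {
  stopifnot(inherits(spec, "instrument_spec"), isTRUE(spec$diagnostic))
  prefix <- tolower(spec$abbreviation)
  items <- as.matrix(cohort[, paste0(prefix, seq_len(spec$n_items))])
  imp <- cohort[[paste0(prefix, "_impair")]] == "yes"
  valid <- stats::complete.cases(items)
  endorsed <- items >= spec$endorsement_threshold
  n_end <- rowSums(endorsed)
  core <- rowSums(endorsed[, spec$core_items, drop = FALSE]) > 0
  symptoms <- core & n_end >= spec$min_endorsed
  case <- ifelse(symptoms, imp, FALSE)     # NA impairment propagates only
  case[!valid] <- NA                       # when symptoms are met
  data.frame(respondent_id = cohort$respondent_id,
             valid = valid,
             sum_score = ifelse(valid, rowSums(items), NA),
             n_endorsed = ifelse(valid, n_end, NA),
             core_met = ifelse(valid, core, NA),
             impairment = imp,
             case = case)
}

comparator_cases <- function(cohort, spec) {
  prefix <- sub("-?[0-9]+$", "", sub("-", "", tolower(spec$abbreviation)))
  items <- as.matrix(cohort[, paste0(prefix, seq_len(spec$n_items))])
  valid <- stats::complete.cases(items)
  score <- ifelse(valid, rowSums(items), NA)
  data.frame(respondent_id = cohort$respondent_id, valid = valid,
             score = score, case = score >= spec$cutoff)
}

item_summary_table <- function(items, spec) {
  k <- spec$max_response
  props <- t(apply(items, 2, function(v) {
    tabulate(factor(v, levels = 0:k), nbins = k + 1) / length(v)
  }))
  itc <- item_total_correlations(items)
  data.frame(item = seq_len(ncol(items)),
             100 * props,
             pct_endorsed = 100 * colMeans(items >= spec$endorsement_threshold),
             mean = colMeans(items), sd = apply(items, 2, sd),
             item_total_r = itc$r_total,
             row.names = NULL) |>
    stats::setNames(c("item", paste0("pct_", 0:k), "pct_endorsed",
                      "mean", "sd", "item_total_r"))
}

#' Run the full validation analysis on a cohort
#'
#' Executes the three-stage analysis on a respondent-level table:
#' (1) item response distributions, endorsement rates, item-total
#' correlations, scale descriptives (mean, SD, skewness with SE), sex
#' t tests, age correlations, treatment-group ANOVAs with Scheffe post
#' hocs and comparator correlations; (2) 1- and 2-parameter normal-ogive
#' IRT models on the binary endorsement recodes, compared by likelihood
#' ratio, with approximate fit indices, McDonald's omega from the 2PL
#' loadings and Cronbach's alpha on the raw items; (3) diagnostic
#' prevalence with Wilson intervals, co-occurrence, and chi-square
#' associations with sex, treatment seeking and PHQ-9/GAD-7 screening
#' caseness.
#'
#' @param cohort A `cohort_table` (from [read_cohort()], [validate_cohort()]
#'   or [simulate_cohort()]).
#' @param conf_level Confidence level for prevalence intervals.
#' @param nodes Gauss-Hermite nodes for the IRT fits.
#' @param min_irt_n Minimum complete cases to attempt IRT (default 100);
#'   below this the IRT section is skipped with a warning and the rest of
#'   the report is produced.
#' @return Object of class `idqiaq_report`.
#' @export
run_full_analysis <- function(cohort, conf_level = 0.95, nodes = 61,
                              min_irt_n = 100) {
  stopifnot(nrow(cohort) > 0)
  if (!inherits(cohort, "cohort_table")) cohort <- validate_cohort(cohort)
  log <- c(attr(cohort, "validation_log"),
           paste0("cohort rows: ", nrow(cohort)))
  specs <- list(IDQ = instrument("IDQ"), IAQ = instrument("IAQ"))
  comps <- list(IDQ = instrument("PHQ9"), IAQ = instrument("GAD7"))
  scales <- list()
  diags <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    prefix <- tolower(nm)
    items_all <- as.matrix(cohort[, paste0(prefix, seq_len(spec$n_items))])
    valid <- stats::complete.cases(items_all)
    log <- c(log, paste0(nm, ": ", sum(!valid),
                         " respondent(s) excluded for missing items"))
    items <- items_all[valid, , drop = FALSE]
    sums <- rowSums(items)
    diag_tab <- diagnose_cohort(cohort, spec)
    diags[[nm]] <- diag_tab

    irt <- NULL
    if (nrow(items) >= min_irt_n) {
      bin <- 1 * (items >= spec$endorsement_threshold)
      if (all(colMeans(bin) > 0 & colMeans(bin) < 1)) {
        fit2 <- irt_probit(bin, "2PL", nodes = nodes)
        fit1 <- irt_probit(bin, "1PL", nodes = nodes, indices = TRUE)
        irt <- list(fit_1pl = fit1, fit_2pl = fit2,
                    comparison = lr_test(fit1, fit2))
      } else {
        warning(nm, ": item(s) without endorsement variation; IRT skipped")
        log <- c(log, paste0(nm, ": IRT skipped (zero-variance items)"))
      }
    } else {
      warning(nm, ": fewer than ", min_irt_n,
              " complete cases; IRT skipped")
      log <- c(log, paste0(nm, ": IRT skipped (too few complete cases)"))
    }
    reliability <- list(alpha = tryCatch(cronbach_alpha(items),
                                         error = function(e) NA_real_))
    if (!is.null(irt)) {
      reliability$omega <- mcdonald_omega(
        discrimination_to_loading(irt$fit_2pl$coefficients$a))
    }
    scales[[nm]] <- list(
      item_table = item_summary_table(items, spec),
      descriptives = describe_scale(sums),
      irt = irt,
      reliability = reliability,
      sum_scores = data.frame(respondent_id = cohort$respondent_id[valid],
                              score = sums)
    )
  }

  # prevalence: determinate diagnoses, counted per scale and jointly
  prev <- list()
  for (nm in names(diags)) {
    d <- diags[[nm]]
    determinate <- d$valid & !is.na(d$case)
    prev[[nm]] <- prevalence_ci(sum(d$case[determinate]),
                                sum(determinate), conf_level)
    prev[[paste0(nm, "_undetermined")]] <- sum(d$valid & is.na(d$case))
  }
  joint <- !is.na(diags$IDQ$case) & !is.na(diags$IAQ$case)
  cd <- diags$IDQ$case[joint]
  ca <- diags$IAQ$case[joint]
  prev$either <- prevalence_ci(sum(cd | ca), sum(joint), conf_level)
  prev$both <- prevalence_ci(sum(cd & ca), sum(joint), conf_level)
  prev$dep_only <- prevalence_ci(sum(cd & !ca), sum(joint), conf_level)
  prev$anx_only <- prevalence_ci(sum(!cd & ca), sum(joint), conf_level)
  prev$co_occurrence <- tryCatch(chisq_assoc(table(IDQ = cd, IAQ = ca)),
                                 error = function(e) NULL)
  prev$pct_dep_also_anx <- 100 * sum(cd & ca) / max(sum(cd), 1)
  prev$pct_anx_also_dep <- 100 * sum(cd & ca) / max(sum(ca), 1)

  # criterion associations
  assoc <- list()
  for (nm in names(specs)) {
    d <- diags[[nm]]
    sums <- scales[[nm]]$sum_scores
    idx <- match(sums$respondent_id, cohort$respondent_id)
    sex <- cohort$sex[idx]
    age <- cohort$age[idx]
    trt <- cohort$treatment_status[idx]
    safe <- function(expr) tryCatch(expr, error = function(e) {
      log <<- c(log, paste0(nm, ": association skipped (", conditionMessage(e), ")"))
      NULL
    })
    a <- list(
      sex_t = safe(pooled_t(sums$score, factor(sex, c("female", "male")))),
      age_r = safe(pearson_r(age, sums$score)),
      treatment_anova = safe(oneway_anova(
        sums$score, factor(trt, c("never", "past", "current", "waitlist"))))
    )
    det <- !is.na(d$case)
    a$sex_case_chisq <- safe(chisq_assoc(table(cohort$sex[det], d$case[det])))
    a$age_case_t <- safe(pooled_t(cohort$age[det],
                                  factor(d$case[det], c(TRUE, FALSE))))
    trt_det <- det & !is.na(cohort$treatment_status)
    a$treatment_case_chisq <- safe(chisq_assoc(
      table(cohort$treatment_status[trt_det], d$case[trt_det])))
    comp <- comparator_cases(cohort, comps[[nm]])
    both_ok <- comp$valid & det
    a$comparator_prevalence <- prevalence_ci(sum(comp$case[both_ok]),
                                             sum(both_ok), conf_level)
    a$comparator_chisq <- safe(chisq_assoc(table(d$case[both_ok],
                                                 comp$case[both_ok])))
    a$pct_cases_also_comparator <- 100 *
      sum(d$case[both_ok] & comp$case[both_ok]) /
      max(sum(d$case[both_ok]), 1)
    a$pct_comparator_also_cases <- 100 *
      sum(d$case[both_ok] & comp$case[both_ok]) /
      max(sum(comp$case[both_ok]), 1)
    a$comparator_r <- safe(pearson_r(sums$score, comp$score[idx]))
    assoc[[nm]] <- a
  }

  structure(list(n = nrow(cohort), scales = scales, prevalence = prev,
                 associations = assoc, diagnoses = diags, log = log,
                 conf_level = conf_level),
            class = "idqiaq_report")
}

#' @export
print.idqiaq_report <- function(x, ...) {
  cat("IDQ/IAQ validation report | n =", x$n, "\n\n")
  for (nm in names(x$scales)) {
    s <- x$scales[[nm]]
    d <- s$descriptives
    cat(sprintf("%s: mean %.2f (SD %.2f), skewness %.2f (se %.2f), range %d-%d\n",
                nm, d$mean, d$sd, d$skewness, d$skewness_se, d$min, d$max))
    cat(sprintf("  alpha %.3f", s$reliability$alpha))
    if (!is.null(s$reliability$omega)) {
      cat(sprintf(", omega (2PL loadings) %.3f", s$reliability$omega))
    }
    cat("\n")
    if (!is.null(s$irt)) {
      cmp <- s$irt$comparison
      cat(sprintf("  1PL vs 2PL: LR chi2(%d) = %.2f, p = %.3g\n",
                  cmp$df_diff, cmp$chi2_diff, cmp$p))
    } else cat("  IRT: skipped\n")
    cat(sprintf("  prevalence: "))
    print(x$prevalence[[nm]])
  }
  cat(sprintf("either %.1f%%, both %.1f%%\n",
              100 * x$prevalence$either$proportion,
              100 * x$prevalence$both$proportion))
  invisible(x)
}

fmt_num <- function(x, d) formatC(x, format = "f", digits = d)

#' Write a report to disk
#'
#' Writes a machine-readable JSON report (full precision), per-scale item
#' tables and IRT parameter/curve CSVs, and a human-readable markdown
#' summary (percentages to 1 decimal, means/SDs to 2, IRT parameters
#' to 3).  Output is deterministic: identical reports produce identical
#' bytes.  When the IRT section was skipped the parameter file contains an
#' explicit `skipped` marker.
#'
#' @param report An `idqiaq_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  paths <- character()
  js <- report_to_list(report)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  irt_rows <- list()
  for (nm in names(report$scales)) {
    s <- report$scales[[nm]]
    p <- file.path(out_dir, paste0("item_table_", nm, ".csv"))
    utils::write.csv(s$item_table, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(s$irt)) {
      co <- s$irt$fit_2pl$coefficients
      irt_rows[[nm]] <- cbind(instrument = nm, co)
      cv <- information_curves(co)
      curve_tab <- data.frame(theta = cv$theta,
                              stats::setNames(as.data.frame(cv$P),
                                              paste0("P_", colnames(cv$P))),
                              stats::setNames(as.data.frame(cv$info),
                                              paste0("I_", colnames(cv$info))),
                              total_info = cv$total_info)
      p <- file.path(out_dir, paste0("curves_", nm, ".csv"))
      utils::write.csv(curve_tab, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(out_dir, "irt_params.csv")
  if (length(irt_rows)) {
    utils::write.csv(do.call(rbind, irt_rows), p, row.names = FALSE)
  } else {
    writeLines("skipped", p)
  }
  paths <- c(paths, p)
  p <- file.path(out_dir, "report.md")
  writeLines(report_markdown(report), p)
  paths <- c(paths, p)
  invisible(paths)
}

# plain-list view of the report for JSON serialization
report_to_list <- function(report) {
  strip_fit <- function(irt) {
    if (is.null(irt)) return("skipped")
    list(
      params_2pl = irt$fit_2pl$coefficients,
      params_1pl = irt$fit_1pl$coefficients,
      loglik = c(`1PL` = irt$fit_1pl$loglik, `2PL` = irt$fit_2pl$loglik),
      converged = c(`1PL` = irt$fit_1pl$converged,
                    `2PL` = irt$fit_2pl$converged),
      lr_test = irt$comparison,
      fit_indices_2pl = unclass(irt$fit_2pl$fit),
      fit_indices_1pl = unclass(irt$fit_1pl$fit))
  }
  strip_gc <- function(g) {
    if (is.null(g)) return(NULL)
    out <- list(statistic = g$statistic, df = g$df, p = g$p,
                method = g$method)
    if (!is.null(g$effect)) out[[g$effect_name]] <- g$effect
    if (!is.null(g$posthoc)) out$posthoc <- g$posthoc
    out
  }
  prev <- lapply(report$prevalence, function(p) {
    if (inherits(p, "prevalence_result")) unclass(p)
    else if (inherits(p, "group_comparison")) strip_gc(p)
    else p
  })
  list(
    n = report$n,
    scales = lapply(report$scales, function(s) list(
      item_table = s$item_table,
      descriptives = s$descriptives,
      reliability = s$reliability,
      irt = strip_fit(s$irt))),
    prevalence = prev,
    associations = lapply(report$associations, function(a)
      lapply(a, function(g) {
        if (inherits(g, "group_comparison")) strip_gc(g)
        else if (inherits(g, "prevalence_result")) unclass(g)
        else g
      })),
    log = report$log)
}

report_markdown <- function(report) {
  out <- c(paste0("# IDQ/IAQ validation report (n = ", report$n, ")"), "")
  for (nm in names(report$scales)) {
    s <- report$scales[[nm]]
    d <- s$descriptives
    out <- c(out, paste0("## ", nm), "",
             paste0("Mean ", fmt_num(d$mean, 2), " (SD ", fmt_num(d$sd, 2),
                    "), skewness ", fmt_num(d$skewness, 2), " (se ",
                    fmt_num(d$skewness_se, 2), "), range ", d$min, "-",
                    d$max, ", n = ", d$n, "."), "")
    it <- s$item_table
    hdr <- c("item", paste0("%", 0:4), "% end.", "M", "SD", "r(it)")
    out <- c(out, paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
    for (i in seq_len(nrow(it))) {
      out <- c(out, paste0(
        "| ", it$item[i], " | ",
        paste(fmt_num(unlist(it[i, paste0("pct_", 0:4)]), 1), collapse = " | "),
        " | ", fmt_num(it$pct_endorsed[i], 1),
        " | ", fmt_num(it$mean[i], 2), " | ", fmt_num(it$sd[i], 2),
        " | ", fmt_num(it$item_total_r[i], 2), " |"))
    }
    out <- c(out, "",
             paste0("Cronbach's alpha ", fmt_num(s$reliability$alpha, 2),
                    if (!is.null(s$reliability$omega))
                      paste0("; McDonald's omega (2PL loadings) ",
                             fmt_num(s$reliability$omega, 2)), "."), "")
    if (!is.null(s$irt)) {
      co <- s$irt$fit_2pl$coefficients
      out <- c(out, "2PL item parameters (a, b with SEs):", "",
               "| item | a | se(a) | b | se(b) |", "|---|---|---|---|---|")
      for (i in seq_len(nrow(co))) {
        out <- c(out, paste0("| ", co$item[i], " | ", fmt_num(co$a[i], 3),
                             " | ", fmt_num(co$se_a[i], 3), " | ",
                             fmt_num(co$b[i], 3), " | ",
                             fmt_num(co$se_b[i], 3), " |"))
      }
      cmp <- s$irt$comparison
      out <- c(out, "",
               paste0("1PL vs 2PL likelihood ratio: chi2(", cmp$df_diff,
                      ") = ", fmt_num(cmp$chi2_diff, 2), ", p = ",
                      format.pval(cmp$p, digits = 3), "."), "")
    } else {
      out <- c(out, "IRT: skipped.", "")
    }
  }
  out <- c(out, "## Prevalence", "")
  for (nm in c("IDQ", "IAQ", "either", "both", "dep_only", "anx_only")) {
    p <- report$prevalence[[nm]]
    out <- c(out, paste0("- ", nm, ": ", fmt_num(100 * p$proportion, 1),
                         "% (", p$n_cases, "/", p$n_total, "; CI ",
                         fmt_num(100 * p$ci_low, 1), "%, ",
                         fmt_num(100 * p$ci_high, 1), "%)"))
  }
  co <- report$prevalence$co_occurrence
  if (!is.null(co)) {
    out <- c(out, paste0("- co-occurrence chi2(", co$df, ") = ",
                         fmt_num(co$statistic, 2), ", p = ",
                         format.pval(co$p, digits = 3)))
  }
  c(out, "")
}
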