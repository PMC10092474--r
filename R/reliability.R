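# Reliability and item-level descriptives.

#' McDonald's omega from standardized loadings
#'
#' `omega = (sum(lambda))^2 / ((sum(lambda))^2 + sum(1 - lambda^2))` for a
#' unidimensional model with standardized loadings `lambda` and
#' uncorrelated residuals.
#'
#' @param loadings Numeric vector of standardized loadings, `|lambda| < 1`.
#' @return Omega in `[0, 1]`.
#' @examples
#' mcdonald_omega(rep(0.9, 9))  # ~0.975
#' @export
mcdonald_omega <- function(loadings) {
  if (length(loadings) == 0) stop("empty loading vector")
  if (any(abs(loadings) >= 1)) stop("|loadings| must be < 1")
  s <- sum(loadings)^2
  s / (s + sum(1 - loadings^2))
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the total)`.
#'
#' @param x Respondents x items numeric matrix (complete cases used).
#' @return Alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("need at least two items")
  vt <- var(rowSums(x))
  if (vt <= 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / vt)
}

#' Item-total correlations
#'
#' Pearson correlation of each item with the scale total, in two variants:
#' `total` correlates the item with the sum including itself (the variant
#' whose magnitudes are conventionally reported in instrument validation
#' tables) and `rest` with the sum of the remaining items.  Items without
#' variance get `NA` with a warning.
#'
#' @param x Respondents x items numeric matrix (complete cases used).
#' @return Data frame with columns `item`, `r_total`, `r_rest`.
#' @export
item_total_correlations <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2 || nrow(x) < 3) stop("need >= 2 items and >= 3 respondents")
  tot <- rowSums(x)
  r_total <- r_rest <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(x))) {
    if (var(x[, j]) == 0) next
    r_total[j] <- cor(x[, j], tot)
    rest <- tot - x[, j]
    r_rest[j] <- if (var(rest) > 0) cor(x[, j], rest) else NA_real_
  }
  if (anyNA(r_total)) warning("zero-variance item(s); correlations set to NA")
  data.frame(item = colnames(x) %||% paste0("item", seq_len(ncol(x))),
             r_total = r_total, r_rest = r_rest, row.names = NULL)
}

#' Sample skewness with standard error
#'
#' Adjusted Fisher-Pearson sample skewness (the small-sample-corrected
#' `G1`, as printed by mainstream statistics packages) with its exact
#' normal-theory standard error
#' `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` and a two-sided normal test of
#' zero skewness.
#'
#' @param x Numeric vector, `n >= 3`, non-constant.
#' @return List with `skewness`, `se`, `z`, `p`, `n`.
#' @examples
#' skewness_se(rep(c(-1, 0, 1), 20))$skewness  # 0
#' @export
skewness_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("skewness undefined for a constant vector")
  s <- e1071::skewness(x, type = 2)
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  z <- s / se
  list(skewness = s, se = se, z = z, p = 2 * pnorm(-abs(z)), n = n)
}

#' Scale descriptives
#'
#' Mean, SD, skewness (+ SE), observed range and n of a score vector.
#'
#' @param x Numeric vector (missing values removed).
#' @return List with `n`, `mean`, `sd`, `skewness`, `skewness_se`,
#'   `min`, `max`.
#' @export
describe_scale <- function(x) {
  x <- x[!is.na(x)]
  sk <- tryCatch(skewness_se(x), error = function(e)
    list(skewness = NA_real_, se = NA_real_, p = NA_real_))
  list(n = length(x), mean = mean(x), sd = sd(x),
       skewness = sk$skewness, skewness_se = sk$se, skewness_p = sk$p,
       min = min(x), max = max(x))
}
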