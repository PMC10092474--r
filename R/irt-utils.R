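# Normal-ogive building blocks: quadrature, tetrachoric correlations,
# parameter conversions, item information, limited-information fit indices.

# Gauss-Hermite rule transformed to integrate against the N(0,1) density:
# sum(w * f(theta)) ~ E[f(theta)], theta ~ N(0,1).
gh_rule <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(theta = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Reference 2PL item parameters for the IDQ and IAQ
#'
#' The published two-parameter normal-ogive estimates from the
#' instruments' initial validation study (UK community sample, N = 2058):
#' per-item discrimination `a` and difficulty `b` on the probit metric
#' with standard errors.  These are the package's default simulation
#' parameters and the anchor for its analytic cross-checks.
#'
#' @param which `"IDQ"`, `"IAQ"`, or `"both"`.
#' @return Data frame with columns `instrument`, `item`, `a`, `se_a`,
#'   `b`, `se_b`.
#' @export
reference_params <- function(which = c("both", "IDQ", "IAQ")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference_params_2pl.csv", package = "idqiaq")
  tab <- utils::read.csv(path, comment.char = "#")
  if (which != "both") tab <- tab[tab$instrument == which, ]
  rownames(tab) <- NULL
  tab
}

#' Reference item response distributions for the IDQ and IAQ
#'
#' Observed per-category response proportions, endorsement percentages and
#' item-total correlations from the instruments' initial validation study.
#' Used to calibrate the synthetic-cohort generator's graded cutpoints.
#'
#' @inheritParams reference_params
#' @return Data frame with columns `instrument`, `item`, `p0`..`p4`,
#'   `pct_endorsed`, `item_total_r`.
#' @export
reference_item_stats <- function(which = c("both", "IDQ", "IAQ")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference_item_stats.csv", package = "idqiaq")
  tab <- utils::read.csv(path, comment.char = "#")
  if (which != "both") tab <- tab[tab$instrument == which, ]
  rownames(tab) <- NULL
  tab
}

#' Model-implied marginal endorsement probability
#'
#' For a binary normal-ogive item with discrimination `a` and difficulty
#' `b` and a standard-normal latent trait, the population endorsement rate
#' has the closed form `pnorm(-a * b / sqrt(1 + a^2))`.  This identity
#' links fitted item parameters back to observed endorsement percentages.
#'
#' @param a,b Discrimination and difficulty (vectors recycle).
#' @return Probability in (0, 1).
#' @examples
#' marginal_endorsement(2.864, 1.190)  # ~0.131
#' @export
marginal_endorsement <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  pnorm(-a * b / sqrt(1 + a^2))
}

#' Normal-ogive parameter conversions
#'
#' Identities linking the IRT slope/difficulty parameterization to the
#' standardized factor-analytic one: loading `lambda = a / sqrt(1 + a^2)`,
#' threshold `tau = a * b / sqrt(1 + a^2)` (both on the latent-response
#' scale with unit total variance).
#'
#' @param a Discrimination(s), probit metric.
#' @param lambda Standardized loading(s), `|lambda| < 1`.
#' @param b Difficulty.
#' @param tau Threshold.
#' @return Converted parameter vector.
#' @name param_conversions
#' @examples
#' loading_to_discrimination(discrimination_to_loading(2.864))  # 2.864
NULL

#' @rdname param_conversions
#' @export
discrimination_to_loading <- function(a) a / sqrt(1 + a^2)

#' @rdname param_conversions
#' @export
loading_to_discrimination <- function(lambda) {
  if (any(abs(lambda) >= 1)) stop("|lambda| must be < 1")
  lambda / sqrt(1 - lambda^2)
}

#' @rdname param_conversions
#' @export
difficulty_to_threshold <- function(a, b) a * b / sqrt(1 + a^2)

#' @rdname param_conversions
#' @export
threshold_to_difficulty <- function(a, tau) tau * sqrt(1 + a^2) / a

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the correlation of the bivariate normal
#' distribution assumed to underlie two dichotomized variables.  Row and
#' column thresholds are fixed at the normal quantiles of the margins;
#' the correlation maximizes the multinomial likelihood of the four cells,
#' with quadrant probabilities from the bivariate normal CDF.
#'
#' A table with a single zero cell gets a continuity correction (0.5 added
#' to every cell) with a warning; a zero margin is an error because the
#' correlation is then undefined.
#'
#' @param tab 2x2 matrix of counts; `tab[2, 2]` is the both-positive cell.
#' @param correct Continuity correction added to all cells when any cell
#'   is zero (default 0.5).
#' @return Correlation in (-1, 1), with attributes `thresholds` (row,
#'   column) and `corrected` (logical).
#' @examples
#' tetrachoric_r(matrix(c(40, 10, 10, 40), 2))  # ~0.81
#' @export
tetrachoric_r <- function(tab, correct = 0.5) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("tetrachoric correlation undefined: a margin of the 2x2 table is zero")
  }
  corrected <- FALSE
  if (any(tab == 0)) {
    warning("zero cell in 2x2 table; continuity correction of ", correct,
            " applied to every cell")
    tab <- tab + correct
    corrected <- TRUE
  }
  n <- sum(tab)
  # thresholds: P(X = 0) = pnorm(h), P(Y = 0) = pnorm(k)
  h <- qnorm(rowSums(tab)[1] / n)
  k <- qnorm(colSums(tab)[1] / n)
  negll <- function(r) {
    p11 <- bvn_upper(h, k, r)           # P(X=1, Y=1)
    p10 <- pnorm(-h) - p11              # P(X=1, Y=0)
    p01 <- pnorm(-k) - p11
    p00 <- 1 - p11 - p10 - p01
    p <- pmax(c(p00, p01, p10, p11), 1e-12)
    -sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
  }
  opt <- optimize(negll, c(-0.9999, 0.9999), tol = 1e-9)
  structure(opt$minimum, thresholds = c(h, k), corrected = corrected)
}

# Upper-quadrant probability P(X > h, Y > k) for standard bivariate normal
# with correlation r.
bvn_upper <- function(h, k, r) {
  mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf),
                   corr = matrix(c(1, r, r, 1), 2))[1]
}

#' Tetrachoric correlation matrix
#'
#' Pairwise tetrachoric correlations for a matrix of binary items, with
#' per-item thresholds (normal quantiles of the non-endorsement rates).
#'
#' @param x Respondents x items matrix of 0/1 values (no missing values).
#' @param correct Continuity correction passed to [tetrachoric_r()].
#' @return Object of class `tetrachoric`: list with `r` (symmetric
#'   correlation matrix, unit diagonal) and `thresholds`.
#' @export
tetrachoric_matrix <- function(x, correct = 0.5) {
  x <- as.matrix(x)
  stopifnot(!anyNA(x), all(x %in% c(0, 1)))
  p <- ncol(x)
  if (p < 2) stop("need at least two items")
  r <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(factor(x[, i], levels = 0:1), factor(x[, j], levels = 0:1))
      r[i, j] <- r[j, i] <- as.numeric(tetrachoric_r(tab, correct))
    }
  }
  dimnames(r) <- list(colnames(x), colnames(x))
  structure(list(r = r, thresholds = qnorm(1 - colMeans(x))),
            class = "tetrachoric")
}

#' @export
print.tetrachoric <- function(x, digits = 3, ...) {
  cat("Tetrachoric correlation matrix (", ncol(x$r), " items)\n", sep = "")
  print(round(x$r, digits))
  cat("Thresholds:", paste(round(x$thresholds, digits), collapse = " "), "\n")
  invisible(x)
}

# One-factor unweighted least squares on a correlation matrix via iterated
# principal factoring; returns standardized loadings with positive mean sign.
uls_onefactor <- function(R, max_iter = 200, tol = 1e-8) {
  p <- ncol(R)
  h <- pmin(apply(abs(R - diag(p)), 1, max), 0.98)^2
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 1e-10)) * e$vectors[, 1]
    h_new <- pmin(lambda^2, 0.9999)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  lambda <- sqrt(h) * sign(e$vectors[, 1])
  if (mean(lambda) < 0) lambda <- -lambda
  lambda
}

#' Item characteristic and information curves
#'
#' For binary normal-ogive items, the characteristic curve is
#' `P(theta) = pnorm(a * (theta - b))` and the Fisher information is
#' `I(theta) = a^2 * dnorm(a * (theta - b))^2 / (P * (1 - P))`.  The total
#' information is the sum over items.
#'
#' @param params Data frame with columns `a` and `b` (one row per item),
#'   e.g. from [reference_params()] or `coef()` on a fitted model.
#' @param theta Numeric grid of latent-trait values.
#' @return Object of class `irt_curves`: list with `theta`, `P`
#'   (grid x items), `info` (grid x items), `total_info`.
#' @examples
#' cv <- information_curves(reference_params("IDQ"), seq(-4, 4, 0.1))
#' cv$theta[which.max(cv$total_info)]  # information peaks above the mean
#' @export
information_curves <- function(params, theta = seq(-4, 4, length.out = 161)) {
  stopifnot(length(theta) >= 1, all(c("a", "b") %in% names(params)))
  a <- params$a
  b <- params$b
  z <- outer(theta, seq_along(a), function(t, j) a[j] * (t - b[j]))
  P <- pnorm(z)
  # upper tail computed directly: P*(1-P) via 1-pnorm underflows first
  Q <- pnorm(z, lower.tail = FALSE)
  info <- sweep(dnorm(z)^2, 2, a^2, "*") / pmax(P * Q, 1e-300)
  nm <- if (!is.null(params$item)) paste0("item", params$item)
        else paste0("item", seq_along(a))
  dimnames(P) <- dimnames(info) <- list(NULL, nm)
  structure(list(theta = theta, P = P, info = info,
                 total_info = rowSums(info)),
            class = "irt_curves")
}

#' @export
as.data.frame.irt_curves <- function(x, ...) {
  data.frame(theta = x$theta,
             P = I(x$P), info = I(x$info),
             total_info = x$total_info)
}

#' Limited-information fit indices
#'
#' Approximate fit indices computed from the discrepancy between an
#' observed tetrachoric correlation matrix and a model-implied correlation
#' matrix: the unweighted least-squares discrepancy `F` (sum of squared
#' below-diagonal residuals) is scaled by `n - 1` into an approximate
#' chi-square; SRMR is the root mean square residual; RMSEA, CFI and TLI
#' are formed from the approximate chi-square with the zero-correlation
#' independence model as baseline.  These are descriptive analogues of the
#' usual estimator-based indices, not their exact equivalents.
#'
#' @param observed Observed correlation matrix (or `tetrachoric` object).
#' @param implied Model-implied correlation matrix.
#' @param n Sample size.
#' @param df Model degrees of freedom; when `df <= 0`, RMSEA and TLI are
#'   reported as `NA`.
#' @return Object of class `fit_indices`: list with `chi2`, `df`, `srmr`,
#'   `rmsea`, `cfi`, `tli`.
#' @export
fit_indices <- function(observed, implied, n, df) {
  if (inherits(observed, "tetrachoric")) observed <- observed$r
  observed <- as.matrix(observed)
  implied <- as.matrix(implied)
  stopifnot(all(dim(observed) == dim(implied)))
  p <- ncol(observed)
  low <- lower.tri(observed)
  resid <- observed[low] - implied[low]
  F_model <- sum(resid^2)
  srmr <- sqrt(mean(resid^2))
  chi2 <- (n - 1) * F_model
  F_base <- sum(observed[low]^2)
  chi2_base <- (n - 1) * F_base
  df_base <- p * (p - 1) / 2
  d_model <- max(chi2 - df, 0)
  d_base <- max(chi2_base - df_base, 0)
  cfi <- if (max(d_model, d_base) == 0) 1 else 1 - d_model / max(d_base, d_model)
  rmsea <- tli <- NA_real_
  if (df > 0) {
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    denom <- chi2_base / df_base - 1
    tli <- if (abs(denom) < 1e-12) NA_real_
           else (chi2_base / df_base - chi2 / df) / denom
  }
  structure(list(chi2 = chi2, df = df, srmr = srmr, rmsea = rmsea,
                 cfi = cfi, tli = tli),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "approx. chi2(%s) = %.2f | SRMR %.3f | RMSEA %s | CFI %.3f | TLI %s\n",
    x$df, x$chi2, x$srmr,
    if (is.na(x$rmsea)) "NA" else sprintf("%.3f", x$rmsea),
    x$cfi,
    if (is.na(x$tli)) "NA" else sprintf("%.3f", x$tli)))
  invisible(x)
}
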