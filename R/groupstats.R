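# Group-comparison statistics: pooled t, one-way ANOVA (raw or from
# published summary statistics) with eta-squared and Scheffe post hocs,
# Pearson chi-square association, product-moment correlation.

new_group_comparison <- function(statistic, df, p, effect_name = NULL,
                                 effect = NULL, method, posthoc = NULL,
                                 extra = list()) {
  structure(c(list(statistic = statistic, df = df, p = p,
                   effect_name = effect_name, effect = effect,
                   method = method, posthoc = posthoc), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(x$method, ": statistic = ", format(round(x$statistic, digits)),
      ", df = ", paste(round(x$df, 2), collapse = ", "),
      ", p = ", format.pval(x$p, digits = digits), sep = "")
  if (!is.null(x$effect)) {
    cat(", ", x$effect_name, " = ", format(round(x$effect, digits)), sep = "")
  }
  cat("\n")
  if (!is.null(x$posthoc)) {
    cat("Scheffe pairwise comparisons:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Pooled-variance two-group t test with Cohen's d
#'
#' Student's t test with pooled variance (df = n1 + n2 - 2, the flavor
#' whose degrees of freedom match conventional reporting) and Cohen's d
#' from the pooled SD.
#'
#' @param values Numeric vector.
#' @param groups Factor-like with exactly two levels; each group needs
#'   `n >= 2`.
#' @return `group_comparison` object (`statistic` = t, `effect` = d).
#' @export
pooled_t <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("each group needs at least 2 observations")
  m <- tapply(values, groups, mean)
  s <- tapply(values, groups, sd)
  pooled_t_summary(n, m, s, labels = levels(groups))
}

#' @rdname pooled_t
#' @param n,means,sds Length-2 vectors of group sizes, means and SDs
#'   (summary-statistics mode).
#' @param labels Optional group labels.
#' @export
pooled_t_summary <- function(n, means, sds, labels = names(n)) {
  stopifnot(length(n) == 2, length(means) == 2, length(sds) == 2)
  sp <- sqrt(((n[1] - 1) * sds[1]^2 + (n[2] - 1) * sds[2]^2) /
               (n[1] + n[2] - 2))
  d <- unname((means[1] - means[2]) / sp)
  t <- unname(d / sqrt(1 / n[1] + 1 / n[2]))
  df <- sum(n) - 2
  new_group_comparison(t, df, 2 * pt(-abs(t), df), "cohen_d", d,
                       method = "Pooled-variance t test",
                       extra = list(groups = labels, pooled_sd = sp))
}

#' One-way ANOVA with eta-squared and Scheffe post hoc tests
#'
#' Computes the one-way analysis of variance either from raw data or from
#' per-group summary statistics `(n, mean, sd)` — the latter reconstructs
#' the between- and within-group sums of squares exactly, so published
#' group tables can be re-analyzed without raw data.  Reports
#' `eta^2 = SSB / (SSB + SSW)` and, optionally, Scheffe-adjusted pairwise
#' comparisons at level `alpha` using the pooled mean square error.
#'
#' @param values,groups Raw-data mode: numeric vector and grouping factor
#'   (each group `n >= 2`).
#' @param summary Summary mode: data frame with columns `group` (optional),
#'   `n`, `mean`, `sd`.
#' @param scheffe Compute the pairwise Scheffe table (default `TRUE`).
#' @param alpha Significance level for the Scheffe decisions (default 0.05).
#' @return `group_comparison` object (`statistic` = F, `df` = c(k-1, N-k),
#'   `effect` = eta-squared, `posthoc` = pairwise table with Scheffe p
#'   values and decisions).
#' @examples
#' oneway_anova(summary = data.frame(
#'   group = c("never", "past", "current", "waitlist"),
#'   n = c(1313, 402, 170, 50),
#'   mean = c(4.88, 10.24, 17.61, 17.98),
#'   sd = c(7.41, 9.52, 9.19, 10.86)))
#' @export
oneway_anova <- function(values = NULL, groups = NULL, summary = NULL,
                         scheffe = TRUE, alpha = 0.05) {
  if (is.null(summary)) {
    keep <- !is.na(values) & !is.na(groups)
    values <- values[keep]
    groups <- droplevels(as.factor(groups[keep]))
    n <- tapply(values, groups, length)
    if (any(n < 2)) stop("each group needs at least 2 observations")
    summary <- data.frame(group = levels(groups), n = as.vector(n),
                          mean = as.vector(tapply(values, groups, mean)),
                          sd = as.vector(tapply(values, groups, sd)))
  }
  stopifnot(all(c("n", "mean", "sd") %in% names(summary)))
  if (is.null(summary$group)) summary$group <- paste0("g", seq_len(nrow(summary)))
  k <- nrow(summary)
  if (k < 2) stop("need at least two groups")
  N <- sum(summary$n)
  gm <- sum(summary$n * summary$mean) / N
  ssb <- sum(summary$n * (summary$mean - gm)^2)
  ssw <- sum((summary$n - 1) * summary$sd^2)
  df1 <- k - 1
  df2 <- N - k
  mse <- ssw / df2
  Fstat <- (ssb / df1) / mse
  eta2 <- ssb / (ssb + ssw)
  posthoc <- NULL
  if (scheffe && k > 2) {
    pairs <- utils::combn(k, 2)
    posthoc <- do.call(rbind, apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      diff <- summary$mean[i] - summary$mean[j]
      # Scheffe: refer diff^2 / (df1 * MSE * (1/ni + 1/nj)) to F(df1, df2)
      Fs <- diff^2 / (df1 * mse * (1 / summary$n[i] + 1 / summary$n[j]))
      p <- pf(Fs, df1, df2, lower.tail = FALSE)
      data.frame(group1 = summary$group[i], group2 = summary$group[j],
                 diff = diff, scheffe_F = Fs, p = p,
                 significant = p < alpha)
    }))
    rownames(posthoc) <- NULL
  }
  new_group_comparison(Fstat, c(df1, df2), pf(Fstat, df1, df2, lower.tail = FALSE),
                       "eta2", eta2, method = "One-way ANOVA",
                       posthoc = posthoc,
                       extra = list(ssb = ssb, ssw = ssw, mse = mse,
                                    groups = summary))
}

#' Pearson chi-square test of association
#'
#' Pearson's chi-square on an r x c contingency table, without continuity
#' correction, df = (r-1)(c-1).  A zero row or column margin is an error.
#'
#' @param tab Matrix (or table) of counts.
#' @return `group_comparison` object (`statistic` = chi-square).
#' @export
chisq_assoc <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square association undefined: zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_group_comparison(unname(ct$statistic), unname(ct$parameter),
                       ct$p.value, method = "Pearson chi-square")
}

#' Pearson product-moment correlation with test
#'
#' Thin wrapper around [stats::cor.test()] returning the correlation, the
#' t-transform test statistic, df and two-sided p value.
#'
#' @param x,y Numeric vectors (pairwise complete, `n >= 3`, non-constant).
#' @return `group_comparison` object (`statistic` = t, `effect` = r).
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  new_group_comparison(unname(ct$statistic), unname(ct$parameter),
                       ct$p.value, "r", unname(ct$estimate),
                       method = "Pearson correlation")
}
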