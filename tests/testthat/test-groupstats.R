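test_that("pooled t: null case, published summaries, raw/summary agreement", {
  v <- rnorm(20)
  same <- pooled_t(c(v, v), rep(c("a", "b"), each = 20))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$effect, 0, tolerance = 1e-12)
  # sex comparison reconstructed from the reference summaries
  ts <- pooled_t_summary(n = c(1069, 983), means = c(8.03, 7.19),
                         sds = c(9.08, 9.40))
  expect_lt(abs(ts$statistic - 2.05), 0.01)
  expect_equal(ts$df, 2050)
  expect_lt(abs(ts$effect - 0.09), 0.005)
  expect_lt(ts$p, 0.05)
  # raw mode equals summary mode on the same data
  set.seed(601)
  vals <- rnorm(300, mean = rep(c(0, 0.4), each = 150))
  grp <- rep(c("x", "y"), each = 150)
  raw <- pooled_t(vals, grp)
  summ <- pooled_t_summary(tapply(vals, grp, length),
                           tapply(vals, grp, mean),
                           tapply(vals, grp, sd))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_error(pooled_t(vals[1:3], c("x", "y", "y")), "at least 2")
  # recovery of a known standardized shift
  set.seed(602)
  big <- c(rnorm(10000), rnorm(10000, 0.5))
  d <- pooled_t(big, rep(c("b", "a"), each = 10000))$effect
  expect_equal(abs(d), 0.5, tolerance = 0.05)
})

test_that("summary-statistics ANOVA reproduces the treatment-group analysis", {
  idq5 <- data.frame(group = c("never", "past", "current", "waitlist"),
                     n = c(1313, 402, 170, 50),
                     mean = c(4.88, 10.24, 17.61, 17.98),
                     sd = c(7.41, 9.52, 9.19, 10.86))
  a <- oneway_anova(summary = idq5)
  expect_lt(abs(a$statistic - 174.81), 0.5)
  expect_equal(a$df, c(3, 1931))
  expect_lt(abs(a$effect - 0.21), 0.005)
  # Scheffe: all pairs differ except current vs waiting list
  ph <- a$posthoc
  cw <- ph$group1 == "current" & ph$group2 == "waitlist"
  expect_false(ph$significant[cw])
  expect_true(all(ph$significant[!cw]))
  iaq5 <- data.frame(group = idq5$group, n = idq5$n,
                     mean = c(5.29, 11.22, 17.22, 17.10),
                     sd = c(6.77, 8.39, 7.93, 9.53))
  expect_lt(abs(oneway_anova(summary = iaq5)$effect - 0.24), 0.005)
})

test_that("ANOVA identities and raw/summary equivalence", {
  set.seed(603)
  vals <- rnorm(240, mean = rep(c(0, 0.2, 0.7), each = 80))
  grp <- rep(c("g1", "g2", "g3"), each = 80)
  raw <- oneway_anova(vals, grp)
  summ <- oneway_anova(summary = data.frame(
    group = c("g1", "g2", "g3"),
    n = as.vector(tapply(vals, grp, length)),
    mean = as.vector(tapply(vals, grp, mean)),
    sd = as.vector(tapply(vals, grp, sd))))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$effect, summ$effect, tolerance = 1e-12)
  # cross-check against stats::aov on the raw data
  av <- summary(stats::aov(vals ~ grp))[[1]]
  expect_equal(raw$statistic, av[["F value"]][1], tolerance = 1e-8)
  # eta2 = F(k-1) / (F(k-1) + N - k)
  k <- 3; N <- length(vals)
  expect_equal(raw$effect,
               raw$statistic * (k - 1) / (raw$statistic * (k - 1) + N - k),
               tolerance = 1e-12)
  # all means equal: F = 0
  null <- oneway_anova(summary = data.frame(n = c(50, 60), mean = c(1, 1),
                                            sd = c(2, 2)))
  expect_equal(null$statistic, 0)
  expect_equal(null$effect, 0)
})

test_that("Scheffe is never more liberal than unadjusted pairwise t", {
  set.seed(604)
  for (rep_i in 1:10) {
    k <- sample(3:5, 1)
    n <- sample(20:60, k, replace = TRUE)
    vals <- unlist(lapply(seq_len(k), function(i)
      rnorm(n[i], mean = runif(1, 0, 0.8))))
    grp <- factor(rep(seq_len(k), n))
    a <- oneway_anova(vals, grp)
    for (rw in seq_len(nrow(a$posthoc))) {
      if (a$posthoc$significant[rw]) {
        i <- as.integer(sub("g", "", a$posthoc$group1[rw]))
        j <- as.integer(sub("g", "", a$posthoc$group2[rw]))
        # unadjusted pairwise t using the pooled MSE
        se <- sqrt(a$mse * (1 / n[i] + 1 / n[j]))
        tstat <- a$posthoc$diff[rw] / se
        p_un <- 2 * pt(-abs(tstat), sum(n) - k)
        expect_lt(p_un, 0.05)
      }
    }
  }
})

test_that("chi-square association matches the hand formula", {
  prop <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(chisq_assoc(prop)$statistic, 0, tolerance = 1e-12)
  tab <- matrix(c(10, 20, 20, 10), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisq_assoc(tab)$statistic, sum((tab - E)^2 / E),
               tolerance = 1e-12)
  expect_equal(chisq_assoc(tab)$df, 1)
  expect_error(chisq_assoc(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("pearson correlation wrapper", {
  x <- rnorm(50)
  expect_equal(pearson_r(x, x)$effect, 1)
  expect_equal(pearson_r(x, -x)$effect, -1)
  set.seed(605)
  n <- 50000
  u <- rnorm(n)
  v <- 0.9 * u + sqrt(1 - 0.81) * rnorm(n)
  expect_equal(pearson_r(u, v)$effect, 0.9, tolerance = 0.005)
  expect_error(pearson_r(x, rep(1, 50)), "zero variance")
})
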