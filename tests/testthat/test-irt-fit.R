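# Estimator behaviour at reduced scale; the full-scale recovery and
# calibration experiments live in test-acceptance.R.

test_that("2PL recovers generating parameters at n = 3000", {
  truth <- reference_params("IDQ")
  dat <- simulate_binary_items(truth, n = 3000, seed = 301)
  fit <- irt_probit(dat, "2PL", se = TRUE, indices = FALSE)
  expect_true(fit$converged)
  # every item within 3 standard errors of its generating value
  expect_true(all(abs(fit$coefficients$a - truth$a) <
                    3 * fit$coefficients$se_a))
  expect_true(all(abs(fit$coefficients$b - truth$b) <
                    3 * fit$coefficients$se_b))
  expect_true(all(fit$coefficients$se_a > 0 & fit$coefficients$se_a < 1))
  expect_true(all(fit$coefficients$se_b > 0 & fit$coefficients$se_b < 0.2))
  # self-consistency: implied endorsement matches observed
  implied <- marginal_endorsement(fit$coefficients$a, fit$coefficients$b)
  expect_true(all(abs(implied - colMeans(dat)) < 0.015))
})

test_that("1PL recovers a common discrimination and respects nesting", {
  truth <- data.frame(a = rep(2, 9), b = reference_params("IDQ")$b)
  dat <- simulate_binary_items(truth, n = 3000, seed = 302)
  f1 <- irt_probit(dat, "1PL", se = TRUE, indices = FALSE)
  f2 <- irt_probit(dat, "2PL", se = FALSE, indices = FALSE)
  expect_equal(f1$coefficients$a[1], 2, tolerance = 0.2 / 2)
  expect_equal(length(unique(f1$coefficients$a)), 1)
  expect_equal(f1$npar, 10)
  expect_equal(f2$npar, 18)
  expect_lte(f1$loglik, f2$loglik)
  # equal-difficulty data: 1PL b estimates agree within sampling error
  truth_eq <- data.frame(a = rep(2, 5), b = rep(1, 5))
  dat_eq <- simulate_binary_items(truth_eq, n = 3000, seed = 303)
  f_eq <- irt_probit(dat_eq, "1PL", se = FALSE, indices = FALSE)
  expect_lt(diff(range(f_eq$coefficients$b)), 0.15)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(irt_probit(matrix(c(0, 1, 1, 0), 4, 1)), "two items")
  expect_error(irt_probit(matrix(c(0.5, 1, 0, 1), 2, 2)), "binary")
  set.seed(304)
  x <- cbind(rbinom(300, 1, 0.4), rbinom(300, 1, 0.5), 0)
  expect_warning(expect_error(irt_probit(x), NA), "without variation")
  # two perfectly correlated items: discrimination driven to the cap
  z <- rbinom(4000, 1, 0.3)
  y <- cbind(z, z, rbinom(4000, 1, 0.4))
  # duplicated items also trigger the tetrachoric continuity warning
  w <- capture_warnings(fcap <- irt_probit(y, se = FALSE, indices = FALSE,
                                           a_max = 10))
  expect_true(any(grepl("upper bound", w)))
  expect_true(all(c(1, 2) %in% fcap$boundary_items))
  expect_true(all(fcap$coefficients$a[1:2] >= 10 - 1e-3))
})

test_that("likelihood-ratio test compares nested fits of the same data", {
  dat <- simulate_binary_items(reference_params("IAQ"), n = 1500, seed = 305)
  f1 <- irt_probit(dat, "1PL", se = FALSE, indices = FALSE)
  f2 <- irt_probit(dat, "2PL", se = FALSE, indices = FALSE)
  lt <- lr_test(f1, f2)
  expect_equal(lt$chi2_diff, 2 * (f2$loglik - f1$loglik), tolerance = 1e-9)
  expect_equal(lt$df_diff, 7)
  expect_gte(lt$chi2_diff, 0)
  # equal log-likelihoods give chi2 = 0, p = 1
  f_same <- f2
  f_same$loglik <- f1$loglik
  lt0 <- lr_test(f1, f_same)
  expect_equal(lt0$chi2_diff, 0)
  expect_equal(lt0$p, 1)
  expect_error(anova(f1, f1), "not nested")
  # different data is refused
  other <- irt_probit(simulate_binary_items(reference_params("IAQ"),
                                            n = 1500, seed = 306),
                      "2PL", se = FALSE, indices = FALSE)
  expect_error(anova(f1, other), "same data")
})

test_that("fitted model reproduces endorsement rates through its own ICC", {
  dat <- simulate_binary_items(reference_params("IAQ"), n = 4000, seed = 307)
  fit <- irt_probit(dat, "2PL", se = FALSE, indices = TRUE)
  co <- fit$coefficients
  expect_true(all(abs(marginal_endorsement(co$a, co$b) - colMeans(dat)) < 0.01))
  # model true: approximate fit indices indicate near-perfect fit
  expect_lt(fit$fit$srmr, 0.05)
  expect_gt(fit$fit$cfi, 0.95)
  # tetrachoric residuals are small
  expect_lt(max(abs(residuals(fit))), 0.2)
})

test_that("methods behave: coef, logLik, predict, simulate", {
  dat <- simulate_binary_items(reference_params("IAQ")[1:4, ], n = 600,
                               seed = 308)
  fit <- irt_probit(dat, "2PL", nodes = 31, se = FALSE, indices = FALSE)
  expect_equal(dim(coef(fit)), c(4, 2))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 8)
  P <- predict(fit, theta = c(-1, 0, 1))
  expect_equal(dim(P), c(3, 4))
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(diff(P[, 1]) > 0))  # ICC monotone in theta
  sims <- simulate(fit, nsim = 2, seed = 1, n = 50)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:1))
})
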