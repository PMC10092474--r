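test_that("latent traits: moments, correlation, determinism, feasibility", {
  cfg <- sim_config(n = 100000, seed = 701)
  set.seed(cfg$seed)
  th <- simulate_thetas(cfg)
  expect_equal(mean(th$theta_dep), 0, tolerance = 0.02)
  expect_equal(sd(th$theta_dep), 1, tolerance = 0.02)
  expect_equal(cor(th$theta_dep, th$theta_anx), 0.75, tolerance = 0.01)
  expect_lt(abs(cor(th$theta_dep, th$age) + 0.33), 0.015)
  # uncorrelated configuration
  cfg0 <- sim_config(n = 100000, seed = 702, trait_correlation = 0,
                     age = list(mean = 46, sd = 16, min = 18, max = 90,
                                r_idq = 0, r_iaq = 0),
                     sex = list(p_female = 0.5, d_idq = 0, d_iaq = 0))
  th0 <- simulate_thetas(cfg0, seed = 1)
  expect_lt(abs(cor(th0$theta_dep, th0$theta_anx)), 0.01)
  # determinism
  expect_identical(simulate_thetas(cfg, n = 100, seed = 9),
                   simulate_thetas(cfg, n = 100, seed = 9))
  expect_error(sim_config(trait_correlation = 1), "< 1")
})

test_that("graded mechanism is consistent with the binary 2PL margin", {
  pars <- reference_params("IDQ")
  cuts <- default_cutpoints("IDQ")
  set.seed(703)
  n <- 50000
  th <- rnorm(n)
  g <- simulate_graded(th, pars, cuts)
  expect_true(all(g %in% 0:4))
  pe <- colMeans(g >= 3)
  pm <- marginal_endorsement(pars$a, pars$b)
  se <- sqrt(pm * (1 - pm) / n)
  expect_true(all(abs(pe - pm) < 3 * se + 1e-9))
  # theta -> +inf: top category
  expect_true(all(simulate_graded(rep(12, 50), pars, cuts) == 4))
  # a = 0: category frequencies equal Phi-differences of the cutpoints
  cuts1 <- matrix(c(-1, 0, 1, 2), 1)
  g0 <- simulate_graded(rnorm(200000), data.frame(a = 0), cuts1)
  expected <- diff(c(0, pnorm(c(-1, 0, 1, 2)), 1))
  expect_equal(as.vector(table(factor(g0, 0:4)) / 200000), expected,
               tolerance = 0.01)
  expect_error(simulate_graded(th[1:5], pars, cuts[, c(2, 1, 3, 4)]),
               "increasing")
})

test_that("impairment model is a probit in theta", {
  set.seed(704)
  th <- rnorm(50000)
  imp <- simulate_impairment(th, 0, 0)
  expect_equal(mean(imp == "yes"), 0.5, tolerance = 0.01)
  imp2 <- simulate_impairment(th, -2, 3)
  expect_gt(mean(imp2[th > 1.5] == "yes"), mean(imp2[th < 0] == "yes"))
})

test_that("default cohort emulates the reference cohort structure", {
  coh <- simulate_cohort(sim_config())  # n = 2058, default seed
  expect_equal(nrow(coh), 2058)
  d <- diagnose_cohort(coh, instrument("IDQ"))
  prev <- mean(d$case, na.rm = TRUE)
  expect_gt(prev, 0.05)
  expect_lt(prev, 0.10)
  # per-item endorsement within 4 points of the reference distribution
  for (w in c("IDQ", "IAQ")) {
    st <- reference_item_stats(w)
    emp <- 100 * colMeans(coh[, paste0(tolower(w), seq_len(nrow(st)))] >= 3)
    expect_true(all(abs(emp - st$pct_endorsed) < 4))
  }
})

test_that("impairment gate: all-no impairment gives zero prevalence", {
  cfg <- sim_config(n = 400, seed = 705,
                    impairment = list(intercept = -50, slope = 0))
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$idq_impair == "no"))
  d <- diagnose_cohort(coh, instrument("IDQ"))
  expect_equal(sum(d$case, na.rm = TRUE), 0)
})

test_that("cohort generation is byte-deterministic", {
  cfg <- sim_config(n = 120, seed = 706)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write.csv(simulate_cohort(cfg), f1, row.names = FALSE, quote = FALSE)
  write.csv(simulate_cohort(cfg), f2, row.names = FALSE, quote = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # the bundled fixture is the n = 500 cohort at the default seed
  fix <- read_cohort(system.file("extdata", "cohort_fixture_n500.csv",
                                 package = "idqiaq"))
  regen <- simulate_cohort(sim_config(n = 500))
  expect_equal(nrow(fix), 500)
  expect_equal(as.data.frame(fix)$idq1, regen$idq1)
  expect_equal(as.data.frame(fix)$treatment_status, regen$treatment_status)
})

test_that("doubling discriminations raises item-total correlations", {
  base_r <- alt_r <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(n = 1500, seed = 710 + s)
    pars2 <- cfg$idq_params
    pars2$a <- pars2$a * 2
    cfg2 <- sim_config(n = 1500, seed = 710 + s, idq_params = pars2)
    base_r[s] <- mean(item_total_correlations(
      simulate_cohort(cfg)[, paste0("idq", 1:9)])$r_total)
    alt_r[s] <- mean(item_total_correlations(
      simulate_cohort(cfg2)[, paste0("idq", 1:9)])$r_total)
  }
  expect_true(all(alt_r > base_r))
})

test_that("end-to-end recovery: fitting simulated cohorts returns the config", {
  cfg <- sim_config(n = 5000, seed = 720)
  coh <- simulate_cohort(cfg)
  bin <- 1 * (as.matrix(coh[, paste0("iaq", 1:8)]) >= 3)
  fit <- irt_probit(bin, "2PL", se = FALSE, indices = FALSE)
  expect_true(all(abs(fit$coefficients$a - cfg$iaq_params$a) < 0.45))
  expect_true(all(abs(fit$coefficients$b - cfg$iaq_params$b) < 0.2))
})
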