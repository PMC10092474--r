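idq <- instrument("IDQ")
iaq <- instrument("IAQ")

test_that("instrument definitions encode the diagnostic constants", {
  expect_equal(idq$n_items, 9)
  expect_equal(iaq$n_items, 8)
  expect_equal(idq$score_max, 36)
  expect_equal(iaq$score_max, 32)
  expect_equal(idq$core_items, 1:2)
  expect_equal(idq$min_endorsed, 5)
  expect_equal(iaq$min_endorsed, 4)
  expect_equal(instrument("PHQ9")$cutoff, 10)
  expect_equal(instrument("GAD7")$n_items, 7)
  expect_length(idq$item_texts, 9)
  expect_error(instrument("FOO"), "unknown instrument")
})

test_that("endorsement dichotomizes at 'Most days' (3)", {
  expect_equal(endorsements(c(0, 1, 2, 3, 4, 0, 0, 0, 0), idq),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(endorsements(rep(0, 9), idq), rep(FALSE, 9))
  expect_equal(endorsements(rep(4, 8), iaq), rep(TRUE, 8))
  expect_error(endorsements(c(0, 5, 0, 0, 0, 0, 0, 0, 0), idq), "item.* 2")
  expect_error(endorsements(rep(0, 8), idq), "9 item")
})

test_that("severity sum scores cover the documented ranges", {
  expect_equal(sum_score(rep(4, 9), idq), 36)
  expect_equal(sum_score(rep(0, 8), iaq), 0)
  expect_equal(sum_score(rep(1, 8), iaq), 8)
  expect_error(sum_score(c(NA, rep(0, 8)), idq), "missing")
})

test_that("depression diagnostic rule: core item, >=5 endorsed, impairment", {
  cases <- list(
    list(v = c(3, 0, 3, 3, 3, 3, 0, 0, 0), imp = TRUE, case = TRUE),
    list(v = c(0, 0, 4, 4, 4, 4, 4, 4, 4), imp = TRUE, case = FALSE),
    list(v = c(4, 4, 4, 4, 3, 0, 0, 0, 0), imp = FALSE, case = FALSE),
    list(v = c(3, 3, 3, 3, 0, 0, 0, 0, 0), imp = TRUE, case = FALSE),
    list(v = rep(4, 9), imp = TRUE, case = TRUE))
  for (cs in cases) {
    expect_identical(diagnose(cs$v, cs$imp, idq)$case, cs$case)
  }
  d <- diagnose(c(3, 0, 3, 3, 3, 3, 0, 0, 0), TRUE, idq)
  expect_equal(d$n_endorsed, 5)
  expect_true(d$core_met)
  expect_equal(d$sum_score, 15)
})

test_that("anxiety diagnostic rule: essential feature, >=4 endorsed, impairment", {
  expect_true(diagnose(c(3, 0, 3, 3, 3, 0, 0, 0), TRUE, iaq)$case)
  expect_false(diagnose(c(3, 3, 3, 0, 0, 0, 0, 0), TRUE, iaq)$case)
  expect_false(diagnose(c(0, 0, 3, 3, 3, 3, 0, 0), TRUE, iaq)$case)
  expect_false(diagnose(c(3, 0, 3, 3, 3, 0, 0, 0), "no", iaq)$case)
  expect_true(diagnose(c(3, 0, 3, 3, 3, 0, 0, 0), "yes", iaq)$case)
})

test_that("missing impairment leaves symptom-positive caseness undetermined", {
  expect_true(is.na(diagnose(rep(4, 9), NA, idq)$case))
  # symptom-negative respondents are non-cases regardless of impairment
  expect_false(diagnose(rep(2, 9), NA, idq)$case)
  expect_false(diagnose(rep(2, 9), TRUE, idq)$case)
})

test_that("diagnosis properties hold on random response vectors", {
  set.seed(401)
  for (spec in list(idq, iaq)) {
    for (i in 1:200) {
      v <- sample(0:4, spec$n_items, replace = TRUE)
      d <- diagnose(v, TRUE, spec)
      # endorsement-count consistency
      expect_equal(d$n_endorsed, sum(endorsements(v, spec)))
      # monotonicity: raising one response never destroys a case
      if (isTRUE(d$case)) {
        j <- sample(spec$n_items, 1)
        v2 <- v
        v2[j] <- min(v2[j] + 1, 4)
        expect_true(diagnose(v2, TRUE, spec)$case)
      }
      # all responses <= 2 can never be a case
      expect_false(diagnose(pmin(v, 2), TRUE, spec)$case)
    }
  }
})

test_that("comparator scoring applies the >=10 screening cut-off", {
  phq <- instrument("PHQ9")
  gad <- instrument("GAD7")
  expect_equal(comparator_case(rep(1, 9), phq), list(score = 9, case = FALSE))
  expect_equal(comparator_case(c(3, 3, 3, 1, 0, 0, 0, 0, 0), phq),
               list(score = 10, case = TRUE))
  expect_equal(comparator_case(rep(3, 7), gad), list(score = 21, case = TRUE))
  expect_error(comparator_case(c(4, rep(0, 8)), phq), "0-3")
})

test_that("prevalence uses the Wilson score interval", {
  p <- prevalence_ci(152, 2058)
  expect_equal(p$proportion, 152 / 2058, tolerance = 1e-12)
  expect_equal(round(100 * p$ci_low, 1), 6.3)
  expect_equal(round(100 * p$ci_high, 1), 8.6)
  # against direct numeric inversion of the score test
  for (xn in list(c(50, 100), c(152, 2058), c(3, 40))) {
    w <- oracle_wilson(xn[1], xn[2])
    p <- prevalence_ci(xn[1], xn[2])
    expect_equal(c(p$ci_low, p$ci_high), w, tolerance = 1e-6)
  }
  p0 <- prevalence_ci(0, 100)
  expect_equal(p0$proportion, 0)
  expect_equal(p0$ci_low, 0)
  expect_error(prevalence_ci(5, 0), "n_total")
  expect_error(prevalence_ci(11, 10), "n_cases")
})

test_that("Wilson interval contains the estimate and shrinks with n", {
  for (ph in c(0.074, 0.3, 0.5)) {
    for (n in c(250, 1000)) {
      x <- round(ph * n)
      p1 <- prevalence_ci(x, n)
      p4 <- prevalence_ci(4 * x, 4 * n)
      expect_true(p1$ci_low <= p1$proportion && p1$proportion <= p1$ci_high)
      expect_lt(p4$ci_high - p4$ci_low, p1$ci_high - p1$ci_low)
    }
  }
})
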