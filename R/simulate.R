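# Synthetic cohort generator.  Emulates the statistical structure of the
# instruments' UK community validation sample (N = 2058): item response
# distributions and 2PL parameters, treatment-group severity separation,
# sex/age associations, impairment gating and ~7% diagnostic caseness --
# so the whole analysis pipeline is testable without the original data.

#' Binary item data from a normal-ogive model
#'
#' Draws respondents x items binary data from
#' `P(X_j = 1 | theta) = pnorm(a_j * (theta - b_j))`, `theta ~ N(0, 1)`.
#'
#' @param params Data frame with columns `a` and `b` (one row per item).
#' @param n Number of respondents.
#' @param theta Optional vector of trait values (overrides `n`).
#' @param seed Optional seed.
#' @return n x items matrix of 0/1 with attribute `"theta"`.
#' @export
simulate_binary_items <- function(params, n, theta = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- rnorm(n)
  n <- length(theta)
  p <- nrow(params)
  P <- pnorm(outer(theta, params$a) -
               matrix(params$a * params$b, n, p, byrow = TRUE))
  x <- matrix(rbinom(n * p, 1, P), n, p)
  colnames(x) <- if (!is.null(params$item)) paste0("item", params$item)
                 else paste0("item", seq_len(p))
  attr(x, "theta") <- theta
  x
}

#' Default graded-response cutpoints
#'
#' Category cutpoints on the standardized latent-response scale for the
#' 0-4 items, back-solved from the reference response distributions: the
#' first, second and fourth cutpoints are normal quantiles of the observed
#' cumulative category proportions, while the third cutpoint is set
#' exactly to the binary threshold `tau = a * b / sqrt(1 + a^2)` so that
#' dichotomizing simulated responses at >= 3 reproduces the 2PL model's
#' marginal endorsement rate by construction.
#'
#' @param which `"IDQ"` or `"IAQ"`.
#' @return Items x 4 matrix of strictly increasing cutpoints.
#' @export
default_cutpoints <- function(which = c("IDQ", "IAQ")) {
  which <- match.arg(which)
  st <- reference_item_stats(which)
  pa <- reference_params(which)
  t1 <- qnorm(st$p0)
  t2 <- qnorm(st$p0 + st$p1)
  t3 <- difficulty_to_threshold(pa$a, pa$b)
  t4 <- qnorm(1 - st$p4)
  m <- cbind(t1, t2, t3, t4)
  rownames(m) <- paste0("item", st$item)
  m
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator.  Defaults encode
#' the reference study's structure: n = 2058 respondents; IDQ/IAQ 2PL
#' parameters and graded cutpoints from the reference tables; a latent
#' depression-anxiety correlation of 0.75; sex effects of d = 0.09 (IDQ)
#' and 0.19 (IAQ); an age-severity correlation of about -0.33; treatment
#' seeking assigned by severity-based selection with group proportions
#' 63.8/19.5/8.3/2.4% (plus 6% missing); a probit impairment model and
#' PHQ-9/GAD-7 comparator items calibrated so that diagnostic caseness
#' falls near 7% and comparator screening caseness near 25%/21%.
#'
#' @param n Number of respondents (>= 10).
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts byte for byte.
#' @param trait_correlation Correlation of the depression and anxiety
#'   traits, in (-1, 1).
#' @param idq_params,iaq_params Data frames with columns `a`, `b`.
#' @param idq_cutpoints,iaq_cutpoints Items x 4 cutpoint matrices.
#' @param impairment Probit model `P(yes | theta) = pnorm(intercept +
#'   slope * theta)` for the impairment answer of each scale.
#' @param sex List: `p_female` and mean shifts `d_idq`, `d_iaq` (Cohen's d
#'   on the latent trait).
#' @param age List: `mean`, `sd`, `min`, `max` of the age distribution and
#'   target trait-age correlations `r_idq`, `r_iaq` (negative: younger
#'   respondents are more symptomatic).
#' @param treatment List: `probs` (never/past/current/waitlist/missing,
#'   summing to 1) and `noise_sd` of the severity-based selection index.
#' @param phq,gad Comparator generators: discrimination `a` and three
#'   cutpoints per item on the standardized latent-response scale.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 2058,
                       seed = 20200323,
                       trait_correlation = 0.75,
                       idq_params = reference_params("IDQ"),
                       iaq_params = reference_params("IAQ"),
                       idq_cutpoints = default_cutpoints("IDQ"),
                       iaq_cutpoints = default_cutpoints("IAQ"),
                       impairment = list(intercept = -2.1, slope = 1.6),
                       sex = list(p_female = 0.521, d_idq = 0.09,
                                  d_iaq = 0.19),
                       age = list(mean = 46, sd = 16, min = 18, max = 90,
                                  r_idq = -0.33, r_iaq = -0.32),
                       treatment = list(
                         probs = c(never = 0.638, past = 0.195,
                                   current = 0.083, waitlist = 0.024,
                                   missing = 0.060),
                         noise_sd = 1.3),
                       phq = list(a = 2.2,
                                  cutpoints = c(0.26, 0.90, 1.50)),
                       gad = list(a = 2.2,
                                  cutpoints = c(0.19, 0.84, 1.44))) {
  if (n < 10) stop("degenerate cohort: n must be at least 10")
  if (abs(trait_correlation) >= 1) stop("|trait_correlation| must be < 1")
  stopifnot(nrow(idq_params) == 9, nrow(iaq_params) == 8,
            all(dim(idq_cutpoints) == c(9, 4)),
            all(dim(iaq_cutpoints) == c(8, 4)),
            abs(sum(treatment$probs) - 1) < 1e-8)
  check_cuts <- function(m) {
    if (any(t(apply(m, 1, diff)) <= 0)) {
      stop("cutpoints must be strictly increasing within each item")
    }
  }
  check_cuts(idq_cutpoints)
  check_cuts(iaq_cutpoints)
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    trait_correlation = trait_correlation,
    idq_params = idq_params, iaq_params = iaq_params,
    idq_cutpoints = idq_cutpoints, iaq_cutpoints = iaq_cutpoints,
    impairment = impairment, sex = sex, age = age, treatment = treatment,
    phq = phq, gad = gad
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration: n =", x$n, ", seed =", x$seed, "\n")
  cat("trait correlation", x$trait_correlation,
      "| impairment probit (", x$impairment$intercept, "+",
      x$impairment$slope, "* theta )\n")
  invisible(x)
}

#' Simulate latent traits with covariate structure
#'
#' Draws per-respondent depression and anxiety traits that are marginally
#' standard normal with the configured correlation, built from three
#' components: a standardized age component (inducing the target negative
#' trait-age correlation), a centered sex shift (females higher by the
#' configured d), and a correlated bivariate-normal residual whose
#' correlation is solved so that the marginal trait correlation equals
#' `trait_correlation` exactly.
#'
#' @param config A [sim_config()].
#' @param n Number of respondents (defaults to `config$n`).
#' @param seed Optional seed (set by [simulate_cohort()] at a higher
#'   level; supply one here for standalone reproducible draws).
#' @return Data frame with `sex`, `age`, `theta_dep`, `theta_anx`.
#' @export
simulate_thetas <- function(config, n = config$n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(config$trait_correlation) >= 1) {
    stop("|trait_correlation| must be < 1")
  }
  sx <- config$sex
  ag <- config$age
  g_d <- -ag$r_idq
  g_a <- -ag$r_iaq
  v_s <- sx$p_female * (1 - sx$p_female)
  s_d <- sqrt(1 - g_d^2 - sx$d_idq^2 * v_s)
  s_a <- sqrt(1 - g_a^2 - sx$d_iaq^2 * v_s)
  rho_e <- (config$trait_correlation - g_d * g_a -
              sx$d_idq * sx$d_iaq * v_s) / (s_d * s_a)
  if (abs(rho_e) >= 1) {
    stop("configuration infeasible: implied residual correlation ",
         round(rho_e, 3), " outside (-1, 1)")
  }
  z_age <- rnorm(n)
  female <- rbinom(n, 1, sx$p_female)
  e1 <- rnorm(n)
  e2 <- rho_e * e1 + sqrt(1 - rho_e^2) * rnorm(n)
  sc <- female - sx$p_female
  theta_dep <- g_d * (-z_age) + sx$d_idq * sc + s_d * e1
  theta_anx <- g_a * (-z_age) + sx$d_iaq * sc + s_a * e2
  age <- pmin(pmax(round(ag$mean + ag$sd * z_age), ag$min), ag$max)
  data.frame(sex = ifelse(female == 1, "female", "male"),
             age = as.integer(age),
             theta_dep = theta_dep, theta_anx = theta_anx)
}

#' Simulate graded (0-4) item responses
#'
#' Latent-response mechanism: for item j the standardized latent response
#' is `(a_j * theta + e) / sqrt(1 + a_j^2)` with standard-normal noise
#' `e`; the observed category is the interval of the item's four ordered
#' cutpoints into which it falls.  Because the third cutpoint of the
#' default configuration equals the binary threshold
#' `a * b / sqrt(1 + a^2)`, dichotomizing at >= 3 is distributionally
#' identical to the binary 2PL model.
#'
#' @param theta Trait vector.
#' @param params Data frame with column `a`.
#' @param cutpoints Items x k matrix of strictly increasing cutpoints
#'   (k = 4 for 0-4 items, k = 3 for the 0-3 comparators).
#' @return Integer matrix of categories 0..k.
#' @export
simulate_graded <- function(theta, params, cutpoints) {
  cutpoints <- as.matrix(cutpoints)
  if (any(t(apply(cutpoints, 1, diff)) <= 0)) {
    stop("cutpoints must be strictly increasing within each item")
  }
  n <- length(theta)
  p <- nrow(cutpoints)
  a <- rep_len(params$a, p)
  out <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    ystar <- (a[j] * theta + rnorm(n)) / sqrt(1 + a[j]^2)
    out[, j] <- findInterval(ystar, cutpoints[j, ])
  }
  out
}

#' Simulate the functional-impairment answer
#'
#' Probit response model `P(yes | theta) = pnorm(intercept + slope *
#' theta)`.
#'
#' @param theta Trait vector.
#' @param intercept,slope Probit coefficients.
#' @return Character vector `"yes"`/`"no"`.
#' @export
simulate_impairment <- function(theta, intercept, slope) {
  yes <- rbinom(length(theta), 1, pnorm(intercept + slope * theta))
  ifelse(yes == 1, "yes", "no")
}

#' Simulate a full cohort
#'
#' Generates a complete respondent-level table: IDQ and IAQ 0-4 items,
#' impairment answers, PHQ-9/GAD-7 comparator items (0-3, driven by the
#' same traits), sex, age and treatment-seeking status.  Treatment status
#' is assigned by severity-based selection: a noisy severity index (mean
#' of the two traits plus Gaussian noise) is cut at the quantiles matching
#' the configured group proportions, which reproduces the strong
#' never < past < current ~ waitlist severity gradient; a configured
#' fraction is missing at random.
#'
#' @param config A [sim_config()]; `config$seed` seeds the whole draw, so
#'   identical configurations give identical cohorts.
#' @return Data frame of class `cohort_table` with columns
#'   `respondent_id`, `idq1`..`idq9`, `idq_impair`, `iaq1`..`iaq8`,
#'   `iaq_impair`, `phq1`..`phq9`, `gad1`..`gad7`, `sex`, `age`,
#'   `treatment_status`.
#' @examples
#' coh <- simulate_cohort(sim_config(n = 300, seed = 1))
#' mean(diagnose_cohort(coh, instrument("IDQ"))$case, na.rm = TRUE)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  th <- simulate_thetas(config, n)
  idq <- simulate_graded(th$theta_dep, config$idq_params,
                         config$idq_cutpoints)
  iaq <- simulate_graded(th$theta_anx, config$iaq_params,
                         config$iaq_cutpoints)
  idq_imp <- simulate_impairment(th$theta_dep, config$impairment$intercept,
                                 config$impairment$slope)
  iaq_imp <- simulate_impairment(th$theta_anx, config$impairment$intercept,
                                 config$impairment$slope)
  phq <- simulate_graded(th$theta_dep, data.frame(a = config$phq$a),
                         matrix(config$phq$cutpoints, 9, 3, byrow = TRUE))
  gad <- simulate_graded(th$theta_anx, data.frame(a = config$gad$a),
                         matrix(config$gad$cutpoints, 7, 3, byrow = TRUE))
  # severity-based treatment selection
  tp <- config$treatment$probs
  idx <- (th$theta_dep + th$theta_anx) / 2 +
    rnorm(n, sd = config$treatment$noise_sd)
  status <- rep(NA_character_, n)
  miss <- runif(n) < tp[["missing"]]
  obs <- which(!miss)
  pr <- tp[c("never", "past", "current", "waitlist")]
  pr <- pr / sum(pr)
  cuts <- quantile(idx[obs], probs = cumsum(pr)[1:3], names = FALSE)
  status[obs] <- c("never", "past", "current", "waitlist")[
    findInterval(idx[obs], cuts) + 1L]
  out <- data.frame(respondent_id = seq_len(n))
  colnames(idq) <- paste0("idq", 1:9)
  colnames(iaq) <- paste0("iaq", 1:8)
  colnames(phq) <- paste0("phq", 1:9)
  colnames(gad) <- paste0("gad", 1:7)
  out <- cbind(out, idq, idq_impair = idq_imp, iaq, iaq_impair = iaq_imp,
               phq, gad)
  out$sex <- th$sex
  out$age <- th$age
  out$treatment_status <- status
  class(out) <- c("cohort_table", "data.frame")
  out
}
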