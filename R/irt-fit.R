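#' Fit a binary normal-ogive IRT model by marginal maximum likelihood
#'
#' Fits the one- or two-parameter normal-ogive model to binary item data:
#' `P(X_j = 1 | theta) = pnorm(a_j * (theta - b_j))` with a standard-normal
#' latent trait (mean 0, variance 1, fixed for identification).  In the
#' one-parameter model the discriminations `a_j` are constrained to be
#' equal; difficulties are free in both models.
#'
#' Estimation is marginal maximum likelihood: the latent trait is
#' integrated out by Gauss-Hermite quadrature and the marginal likelihood
#' is maximized by an EM algorithm (Bock-Aitkin), started deterministically
#' from a one-factor unweighted least-squares solution on the tetrachoric
#' correlation matrix, and finished with a quasi-Newton polish of the
#' marginal log-likelihood (analytic gradient via Fisher's identity).
#' Standard errors come from the observed information matrix at the
#' optimum.  Discriminations are capped at `a_max` to contain Heywood-type
#' boundary behaviour; items hitting the cap are flagged.
#'
#' @param x Respondents x items matrix (or data frame) of 0/1 values.
#'   Rows with missing values are dropped (complete-case); items with no
#'   variation are excluded with a warning.
#' @param model `"2PL"` (default) or `"1PL"`.
#' @param nodes Number of Gauss-Hermite quadrature nodes (default 61).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-7).
#' @param a_max Upper bound on discriminations (default 10).
#' @param se Compute standard errors (default `TRUE`).
#' @param indices Compute the observed tetrachoric matrix and approximate
#'   fit indices (default `TRUE`; disable in tight simulation loops).
#' @param start `"tetrachoric"` (default) for the deterministic
#'   limited-information start, or `"margins"` for a cheap start from the
#'   item endorsement rates alone.
#' @return An object of class `irt_probit` with components `coefficients`
#'   (data frame: `item`, `a`, `se_a`, `b`, `se_b`), `model`, `loglik`,
#'   `npar`, `n`, `n_items`, `converged`, `boundary_items`, `fit`
#'   (approximate fit indices, or `NULL`), `tetrachoric` (or `NULL`),
#'   `quad` (nodes used) and the collapsed response-pattern table.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `anova` (likelihood
#'   ratio test between nested fits), `predict` (item probabilities at
#'   given trait values), `plot` (characteristic and information curves),
#'   `simulate`, `residuals` (tetrachoric residuals).
#' @examples
#' set.seed(7)
#' dat <- simulate_binary_items(reference_params("IDQ"), n = 400)
#' fit <- irt_probit(dat, nodes = 31, se = FALSE, indices = FALSE)
#' coef(fit)
#' @export
irt_probit <- function(x, model = c("2PL", "1PL"), nodes = 61,
                       max_iter = 500, tol = 1e-7, a_max = 10,
                       se = TRUE, indices = TRUE,
                       start = c("tetrachoric", "margins")) {
  model <- match.arg(model)
  start <- match.arg(start)
  cl <- match.call()
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped (complete-case)")
    x <- x[keep, , drop = FALSE]
  }
  if (!all(x %in% c(0, 1))) stop("data must be binary 0/1")
  n <- nrow(x)
  if (n < 2) stop("too few respondents")
  pbar <- colMeans(x)
  degenerate <- pbar <= 0 | pbar >= 1
  if (any(degenerate)) {
    warning("item(s) without variation excluded: ",
            paste(colnames(x)[degenerate] %||% which(degenerate),
                  collapse = ", "))
    x <- x[, !degenerate, drop = FALSE]
    pbar <- pbar[!degenerate]
  }
  p <- ncol(x)
  if (p < 2) stop("at least two items with variation are required")
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(p))

  # collapse to unique response patterns
  key <- as.vector(x %*% 2^(seq_len(p) - 1))
  o <- order(key)
  ux <- x[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  cnt <- as.vector(table(factor(key, levels = unique(key[o]))))
  quad <- gh_rule(nodes)

  # deterministic start values
  tet <- NULL
  if (start == "tetrachoric") {
    tet <- tetrachoric_matrix(x)
    lambda <- pmin(abs(uls_onefactor(tet$r)), 0.995)
    a0 <- pmin(loading_to_discrimination(lambda), a_max)
    beta0 <- -tet$thresholds * sqrt(1 + a0^2)
  } else {
    a0 <- rep(1.2, p)
    beta0 <- qnorm(pbar) * sqrt(1 + a0^2)
  }
  if (model == "1PL") {
    a_common <- mean(a0)
    a0 <- rep(a_common, p)
    beta0 <- qnorm(pbar) * sqrt(1 + a_common^2)
  }

  em <- em_mml(ux, cnt, a0, beta0, quad, model, max_iter, tol, a_max)
  pol <- polish_mml(ux, cnt, em$alpha, em$beta, quad, model, a_max)
  alpha <- pol$alpha
  beta <- pol$beta
  loglik <- pol$loglik
  boundary <- which(alpha >= a_max - 1e-4)
  if (length(boundary)) {
    warning("discrimination at upper bound (", a_max, ") for item(s) ",
            paste(colnames(x)[boundary], collapse = ", "),
            "; estimates are boundary values")
  }

  b <- -beta / alpha
  npar <- if (model == "2PL") 2L * p else p + 1L
  ses <- if (se) mml_standard_errors(ux, cnt, alpha, beta, quad, model)
         else list(se_a = rep(NA_real_, p), se_b = rep(NA_real_, p))

  coefs <- data.frame(item = colnames(x), a = alpha, se_a = ses$se_a,
                      b = b, se_b = ses$se_b, row.names = NULL)
  fit_ix <- NULL
  if (indices) {
    if (is.null(tet)) tet <- tetrachoric_matrix(x)
    lam <- discrimination_to_loading(alpha)
    implied <- tcrossprod(lam)
    diag(implied) <- 1
    df <- p * (p + 1) / 2 - npar
    fit_ix <- fit_indices(tet$r, implied, n, df)
  }
  structure(list(
    coefficients = coefs, model = model, loglik = loglik, npar = npar,
    n = n, n_items = p, converged = em$converged && pol$converged,
    em_iterations = em$iter, boundary_items = boundary,
    fit = fit_ix, tetrachoric = tet,
    quad_nodes = nodes, a_max = a_max,
    patterns = list(x = ux, count = cnt),
    call = cl
  ), class = "irt_probit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- marginal likelihood machinery -----------------------------------------

# log P matrices for all nodes x items; clamped away from 0/1
prob_nodes <- function(alpha, beta, theta) {
  z <- outer(theta, alpha) + matrix(beta, length(theta), length(beta),
                                    byrow = TRUE)
  P <- pnorm(z)
  pmin(pmax(P, 1e-12), 1 - 1e-12)
}

# E-step quantities: marginal loglik, expected node totals n_q and
# per-item endorsement counts r (items x nodes)
estep <- function(ux, cnt, alpha, beta, quad) {
  P <- prob_nodes(alpha, beta, quad$theta)      # nodes x items
  lp <- log(P)
  lq <- log1p(-P)
  ll_pq <- tcrossprod(ux, lp) + tcrossprod(1 - ux, lq)  # patterns x nodes
  ll_pq <- sweep(ll_pq, 2, log(quad$w), "+")
  m <- apply(ll_pq, 1, max)
  W <- exp(ll_pq - m)
  rs <- rowSums(W)
  loglik <- sum(cnt * (m + log(rs)))
  W <- W / rs                                    # posterior weights
  cw <- cnt * W
  list(loglik = loglik, P = P,
       n_q = colSums(cw),
       r = crossprod(ux, cw))                    # items x nodes
}

# Newton update of (alpha_j, beta_j) for one item on expected counts
newton_item <- function(aj, bj, r_j, n_q, theta, a_max, iters = 3) {
  for (it in seq_len(iters)) {
    z <- aj * theta + bj
    P <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
    phi <- dnorm(z)
    u <- (r_j - n_q * P) * phi / (P * (1 - P))
    g <- c(sum(u * theta), sum(u))
    w <- n_q * phi^2 / (P * (1 - P))
    H <- matrix(c(sum(w * theta^2), sum(w * theta),
                  sum(w * theta), sum(w)), 2)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H), 1e-8))
    # damp the step: an undamped jump from a flat region can overshoot
    # into the a = 0 saddle and stall there
    step <- pmin(pmax(step, -1), 1)
    aj <- min(max(aj + step[1], 1e-3), a_max)
    bj <- min(max(bj + step[2], -30), 30)
  }
  c(aj, bj)
}

em_mml <- function(ux, cnt, alpha, beta, quad, model, max_iter, tol, a_max) {
  p <- length(alpha)
  theta <- quad$theta
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    e <- estep(ux, cnt, alpha, beta, quad)
    if (is.finite(ll_old) &&
        abs(e$loglik - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- e$loglik
    if (model == "2PL") {
      for (j in seq_len(p)) {
        ab <- newton_item(alpha[j], beta[j], e$r[j, ], e$n_q, theta, a_max)
        alpha[j] <- ab[1]
        beta[j] <- ab[2]
      }
    } else {
      # ECM for the constrained model: betas given alpha, then common alpha
      for (cycle in 1:2) {
        for (j in seq_len(p)) {
          ab <- newton_item(alpha[j], beta[j], e$r[j, ], e$n_q, theta, a_max,
                            iters = 2)
          beta[j] <- ab[2]
        }
        a <- alpha[1]
        for (nw in 1:3) {
          g <- 0; h <- 0
          for (j in seq_len(p)) {
            z <- a * theta + beta[j]
            P <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
            phi <- dnorm(z)
            g <- g + sum((e$r[j, ] - e$n_q * P) * phi / (P * (1 - P)) * theta)
            h <- h + sum(e$n_q * phi^2 / (P * (1 - P)) * theta^2)
          }
          a <- min(max(a + min(max(g / h, -1), 1), 1e-3), a_max)
        }
        alpha <- rep(a, p)
      }
    }
  }
  list(alpha = alpha, beta = beta, loglik = ll_old,
       converged = converged, iter = iter)
}

# pack/unpack between the optimizer vector and (alpha, beta)
pack_par <- function(alpha, beta, model) {
  if (model == "2PL") c(alpha, beta) else c(alpha[1], beta)
}
unpack_par <- function(par, p, model) {
  if (model == "2PL") list(alpha = par[seq_len(p)], beta = par[p + seq_len(p)])
  else list(alpha = rep(par[1], p), beta = par[-1])
}

neg_loglik_mml <- function(par, ux, cnt, quad, n_items, model) {
  pr <- unpack_par(par, n_items, model)
  -estep(ux, cnt, pr$alpha, pr$beta, quad)$loglik
}

# gradient of the negative marginal loglik (Fisher's identity: the
# observed-data score equals the expected complete-data score)
neg_grad_mml <- function(par, ux, cnt, quad, n_items, model) {
  pr <- unpack_par(par, n_items, model)
  e <- estep(ux, cnt, pr$alpha, pr$beta, quad)
  theta <- quad$theta
  z <- outer(theta, pr$alpha) + matrix(pr$beta, length(theta), n_items, byrow = TRUE)
  P <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
  U <- (t(e$r) - e$n_q * P) * dnorm(z) / (P * (1 - P))  # nodes x items
  g_alpha <- colSums(U * theta)
  g_beta <- colSums(U)
  if (model == "2PL") -c(g_alpha, g_beta) else -c(sum(g_alpha), g_beta)
}

polish_mml <- function(ux, cnt, alpha, beta, quad, model, a_max) {
  p <- length(alpha)
  par <- pack_par(alpha, beta, model)
  n_a <- if (model == "2PL") p else 1L
  lower <- c(rep(1e-3, n_a), rep(-30, p))
  upper <- c(rep(a_max, n_a), rep(30, p))
  opt <- optim(par, neg_loglik_mml, neg_grad_mml,
               ux = ux, cnt = cnt, quad = quad, n_items = p, model = model,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 200, factr = 1e4))
  pr <- unpack_par(opt$par, p, model)
  list(alpha = pr$alpha, beta = pr$beta, loglik = -opt$value,
       converged = opt$convergence %in% c(0L, 52L))
}

mml_standard_errors <- function(ux, cnt, alpha, beta, quad, model) {
  p <- length(alpha)
  par <- pack_par(alpha, beta, model)
  H <- tryCatch(
    optimHess(par, neg_loglik_mml, neg_grad_mml,
              ux = ux, cnt = cnt, quad = quad, n_items = p, model = model),
    error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    warning("observed information not positive definite; ",
            "standard errors unavailable")
    return(list(se_a = rep(NA_real_, p), se_b = rep(NA_real_, p)))
  }
  if (model == "2PL") {
    se_a <- sqrt(diag(V)[seq_len(p)])
    se_b <- vapply(seq_len(p), function(j) {
      idx <- c(j, p + j)                         # (alpha_j, beta_j)
      J <- c(beta[j] / alpha[j]^2, -1 / alpha[j])  # d b / d(alpha, beta)
      sqrt(max(t(J) %*% V[idx, idx] %*% J, 0))
    }, numeric(1))
  } else {
    se_a <- rep(sqrt(diag(V)[1]), p)
    se_b <- vapply(seq_len(p), function(j) {
      idx <- c(1L, 1L + j)
      J <- c(beta[j] / alpha[1]^2, -1 / alpha[1])
      sqrt(max(t(J) %*% V[idx, idx] %*% J, 0))
    }, numeric(1))
  }
  list(se_a = se_a, se_b = se_b)
}

# --- methods ---------------------------------------------------------------

#' @export
print.irt_probit <- function(x, digits = 3, ...) {
  cat("Normal-ogive ", x$model, " model (marginal ML, ", x$quad_nodes,
      "-node Gauss-Hermite)\n", sep = "")
  cat(x$n, "respondents,", x$n_items, "items; log-likelihood",
      format(x$loglik, digits = 8), "\n")
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.irt_probit <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("a", "b")])
  rownames(m) <- object$coefficients$item
  m
}

#' @export
logLik.irt_probit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
summary.irt_probit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, model = object$model,
              loglik = object$loglik, npar = object$npar, n = object$n,
              converged = object$converged, fit = object$fit,
              boundary_items = object$boundary_items,
              marginal = marginal_endorsement(object$coefficients$a,
                                              object$coefficients$b))
  class(out) <- "summary.irt_probit"
  out
}

#' @export
print.summary.irt_probit <- function(x, digits = 3, ...) {
  cat("Normal-ogive", x$model, "model |", x$n, "respondents |",
      "log-likelihood", format(x$loglik, digits = 8), "|",
      x$npar, "parameters\n")
  tab <- x$coefficients
  tab$implied_endorse <- x$marginal
  print(cbind(tab[1], round(tab[-1], digits)), row.names = FALSE)
  if (length(x$boundary_items)) {
    cat("Boundary discrimination for item(s):",
        paste(x$boundary_items, collapse = ", "), "\n")
  }
  if (!is.null(x$fit)) print(x$fit)
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' Likelihood-ratio test between nested normal-ogive fits
#'
#' Compares a 1PL (equal-discrimination) fit with a 2PL fit of the same
#' data: twice the log-likelihood difference is referred to a chi-square
#' with degrees of freedom equal to the parameter-count difference.  The
#' fits must come from identical data (checked on the collapsed response
#' patterns).
#'
#' @param object,... Two `irt_probit` fits in either order.
#' @return Data frame of class `anova` with log-likelihoods, the
#'   chi-square difference, df and p value.
#' @export
anova.irt_probit <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- Filter(function(f) inherits(f, "irt_probit"), fits)
  if (length(fits) != 2) stop("supply exactly two irt_probit fits")
  fits <- fits[order(vapply(fits, `[[`, 0L, "npar"))]
  restricted <- fits[[1]]
  full <- fits[[2]]
  if (restricted$npar == full$npar) stop("models are not nested")
  same <- identical(dim(restricted$patterns$x), dim(full$patterns$x)) &&
    identical(restricted$patterns$count, full$patterns$count) &&
    all(restricted$patterns$x == full$patterns$x)
  if (!same) stop("fits are not based on the same data")
  chi2 <- 2 * (full$loglik - restricted$loglik)
  if (chi2 < -1e-6 * max(1, abs(full$loglik))) {
    stop("restricted model has higher likelihood; models are not nested ",
         "or estimation failed")
  }
  chi2 <- max(chi2, 0)
  df <- full$npar - restricted$npar
  p <- pchisq(chi2, df, lower.tail = FALSE)
  out <- data.frame(
    npar = c(restricted$npar, full$npar),
    logLik = c(restricted$loglik, full$loglik),
    chi2 = c(NA, chi2), df = c(NA, df), p_value = c(NA, p),
    row.names = c(restricted$model, full$model))
  class(out) <- c("anova", "data.frame")
  attr(out, "heading") <- "Likelihood-ratio test (marginal ML)"
  out
}

#' @rdname anova.irt_probit
#' @param fit_restricted,fit_full The constrained (1PL) and unconstrained
#'   (2PL) fits.
#' @export
lr_test <- function(fit_restricted, fit_full) {
  if (fit_restricted$npar >= fit_full$npar) {
    stop("fit_restricted must have fewer parameters than fit_full")
  }
  a <- anova(fit_restricted, fit_full)
  list(chi2_diff = a$chi2[2], df_diff = a$df[2], p = a$p_value[2])
}

#' @export
predict.irt_probit <- function(object, theta = seq(-4, 4, length.out = 161),
                               ...) {
  cv <- information_curves(object$coefficients, theta)
  cv$P
}

#' @export
plot.irt_probit <- function(x, theta = seq(-4, 4, length.out = 161), ...) {
  cv <- information_curves(x$coefficients, theta)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(cv$theta, cv$P, type = "l", lty = 1,
                    xlab = expression(theta), ylab = "P(endorse)",
                    main = paste(x$model, "item characteristic curves"))
  graphics::plot(cv$theta, cv$total_info, type = "l",
                 xlab = expression(theta), ylab = "Information",
                 main = "Total information")
  invisible(cv)
}

#' @export
residuals.irt_probit <- function(object, ...) {
  if (is.null(object$tetrachoric)) {
    stop("fit was run with indices = FALSE; tetrachoric residuals unavailable")
  }
  lam <- discrimination_to_loading(object$coefficients$a)
  implied <- tcrossprod(lam)
  diag(implied) <- 1
  object$tetrachoric$r - implied
}

#' @export
simulate.irt_probit <- function(object, nsim = 1, seed = NULL,
                                n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_binary_items(object$coefficients, n),
            simplify = FALSE)
}
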