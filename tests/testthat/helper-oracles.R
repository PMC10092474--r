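# Independent numerical oracles used by the tests.  These deliberately
# avoid the code paths they check: the orthant probability is a 1-D
# integral reduction (not the bivariate-CDF routine the package uses), and
# the Wilson bounds come from direct root-finding on the score test.

# P(X > h, Y > k) for standard bivariate normal, via conditioning on X
oracle_orthant <- function(h, k, r) {
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((r * x - k) / sqrt(1 - r^2))
  }, h, Inf, rel.tol = 1e-10)$value
}

# brute-force tetrachoric MLE: coarse grid then local refinement
oracle_tetrachoric <- function(tab) {
  n <- sum(tab)
  h <- stats::qnorm(rowSums(tab)[1] / n)
  k <- stats::qnorm(colSums(tab)[1] / n)
  ll <- function(r) {
    p11 <- oracle_orthant(h, k, r)
    p10 <- stats::pnorm(-h) - p11
    p01 <- stats::pnorm(-k) - p11
    p00 <- 1 - p11 - p10 - p01
    p <- pmax(c(p00, p01, p10, p11), 1e-12)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
  }
  coarse <- seq(-0.99, 0.99, by = 0.01)
  r0 <- coarse[which.max(vapply(coarse, ll, 0))]
  fine <- seq(max(-0.995, r0 - 0.012), min(0.995, r0 + 0.012), by = 2e-4)
  fine[which.max(vapply(fine, ll, 0))]
}

# Wilson bounds by direct numeric inversion of the score test
oracle_wilson <- function(x, n, conf = 0.95) {
  phat <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  lo <- if (phat == 0) 0 else stats::uniroot(g, c(1e-12, phat), tol = 1e-12)$root
  hi <- if (phat == 1) 1 else stats::uniroot(g, c(phat, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# random 2x2 table from a dichotomized bivariate normal (both margins
# guaranteed nonzero by rejection)
random_2x2 <- function(n, rho, h, k) {
  repeat {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    tab <- table(factor(x > h, c(FALSE, TRUE)), factor(y > k, c(FALSE, TRUE)))
    tab <- matrix(as.integer(tab), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
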