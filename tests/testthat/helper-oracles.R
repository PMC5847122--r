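# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of the closed form,
# sampling instead of normal-theory integrals.

# second moment of the standard normal over [x1, x0] by adaptive quadrature
quad_tail_moment <- function(x0, x1) {
  stats::integrate(function(z) z^2 * stats::dnorm(z), x1, x0,
                   rel.tol = 1e-12)$value
}

# closed-form case/control mean-risk gap for a calibrated score: the
# liability integral collapses because a normal prior on the score mixes
# with the probit risk into a single probit
risk_gap_closed_form <- function(r2, K) {
  tau <- stats::qnorm(1 - K)
  cm <- prsproject::conditional_moments(r2, K)
  gap <- function(mu, v) stats::pnorm((mu - tau) / sqrt(1 - r2 + v))
  gap(cm$mean_case, cm$var_case) - gap(cm$mean_control, cm$var_control)
}

# Monte-Carlo rectangle probability for a zero-mean MVN
mc_mvn_rectangle <- function(lo, hi, S, n = 1e6, seed = 1) {
  set.seed(seed)
  L <- chol(S)
  Z <- matrix(stats::rnorm(n * nrow(S)), n) %*% L
  inside <- rep(TRUE, n)
  for (j in seq_len(ncol(Z))) {
    inside <- inside & Z[, j] > lo[j] & Z[, j] <= hi[j]
  }
  p <- mean(inside)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# draw (liability, calibrated score) pairs under the bivariate normal
# implied by a liability R2 of r2
draw_liability_score <- function(n, r2, seed) {
  set.seed(seed)
  l <- stats::rnorm(n)
  s <- r2 * l + stats::rnorm(n, 0, sqrt(r2 * (1 - r2)))
  data.frame(l = l, s = s)
}

expect_within_3se <- function(est, target, se, label = "estimate") {
  expect_lt(abs(est - target), 3 * se + 1e-12,
            label = sprintf("%s = %g vs %g (3se = %g)", label, est, target, 3 * se))
}
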