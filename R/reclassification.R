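#' Absolute risk implied by a calibrated score value
#'
#' Under the liability-threshold model a calibrated score `x` with
#' liability R-squared `r2` leaves residual liability variance `1 - r2`,
#' so the absolute risk is `1 - pnorm((tau - x) / sqrt(1 - r2))`.
#' [score_at_risk()] is the exact inverse: the score value whose risk
#' equals a target threshold `a`, `tau - sqrt(1 - r2) * qnorm(1 - a)`.
#'
#' @param x Calibrated score value(s).
#' @param r2 Liability R-squared of the score, below 1.
#' @param K Disease prevalence.
#' @return Absolute risks in `(0, 1)`.
#' @examples
#' risk_from_score(0, r2 = 0, K = 0.15)  # baseline risk = prevalence
#' @export
risk_from_score <- function(x, r2, K) {
  if (r2 >= 1) abort("`r2` must be below 1.")
  tau <- qnorm(1 - K)
  1 - pnorm((tau - x) / sqrt(1 - r2))
}

#' @rdname risk_from_score
#' @param a Absolute-risk threshold(s) in `(0, 1)`.
#' @export
score_at_risk <- function(a, r2, K) {
  if (r2 >= 1) abort("`r2` must be below 1.")
  tau <- qnorm(1 - K)
  tau - sqrt(1 - r2) * qnorm(1 - a)
}

#' Joint distribution of liability, environmental and combined scores
#'
#' The liability `Y`, the environmental score `X` and the calibrated
#' combined score `gamma * S_comb` are jointly normal with mean zero and
#' covariance
#' `[[1, r2_xy, r2_comb], [r2_xy, r2_xy, cov_gcomb_x],
#'   [r2_comb, cov_gcomb_x, r2_comb]]`
#' (a calibrated score covaries with liability by its own variance).
#' The matrix is checked for symmetry and positive semi-definiteness;
#' failure signals inconsistent parameters.
#'
#' @param comb A [combine_scores()] result.
#' @return A 3x3 covariance matrix with dimnames `y`, `x`, `s`.
#' @export
trivariate_joint <- function(comb) {
  stopifnot(inherits(comb, "combined_score"))
  S <- matrix(c(
    1, comb$r2_xy, comb$r2_comb,
    comb$r2_xy, comb$r2_xy, comb$cov_gcomb_x,
    comb$r2_comb, comb$cov_gcomb_x, comb$r2_comb
  ), 3, 3, dimnames = list(c("y", "x", "s"), c("y", "x", "s")))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort("joint covariance of liability and scores is not positive semi-definite; inconsistent parameters.")
  }
  S
}

# ---- deterministic multivariate-normal rectangles ------------------------

# bivariate normal CDF, deterministic (TVPACK)
pbvn <- function(h, k, rho) {
  if (h <= -37 || k <= -37) return(0)
  h <- min(h, 37); k <- min(k, 37)
  rho <- max(-1 + 1e-15, min(1 - 1e-15, rho))
  as.numeric(mvtnorm::pmvnorm(
    upper = c(h, k), corr = matrix(c(1, rho, rho, 1), 2),
    algorithm = mvtnorm::TVPACK(abseps = 1e-12)
  ))
}

# trivariate normal CDF, deterministic (TVPACK)
ptvn <- function(u, R) {
  if (any(u <= -37)) return(0)
  u <- pmin(u, 37)
  as.numeric(mvtnorm::pmvnorm(
    upper = u, corr = R, algorithm = mvtnorm::TVPACK(abseps = 1e-8)
  ))
}

# P(lo < Z <= hi) for trivariate normal with covariance S, by
# inclusion-exclusion over 8 CDF calls; tiny negatives clipped to 0
mvn_rectangle <- function(lo, hi, S) {
  sd <- sqrt(diag(S))
  R <- S / tcrossprod(sd)
  diag(R) <- 1
  lo <- lo / sd
  hi <- hi / sd
  tot <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    u <- c(
      if (i) lo[1] else hi[1],
      if (j) lo[2] else hi[2],
      if (k) lo[3] else hi[3]
    )
    if (any(u == -Inf)) next
    tot <- tot + (-1)^(i + j + k) * ptvn(u, R)
  }
  max(tot, 0)
}

#' Categorical net reclassification improvement
#'
#' Two risk categories are defined by an absolute-risk threshold `a`. The
#' case NRI is the probability that a case moves above the threshold when
#' the environmental score is replaced by the calibrated combined score,
#' minus the probability that it moves below; the control NRI is the
#' mirror image. Both are rectangle probabilities of the trivariate normal
#' joint distribution of liability, environmental score, and calibrated
#' combined score, divided by `K` (cases) or `1 - K` (controls). The
#' score-scale thresholds are the [score_at_risk()] inverses for the two
#' scores. Rectangles are evaluated by inclusion-exclusion over
#' deterministic trivariate-normal CDF calls.
#'
#' @param comb A [combine_scores()] result.
#' @param trait A binary [trait_model()].
#' @param a Absolute-risk threshold(s) in `(0, 1)`, vectorized.
#' @return A tibble with columns `a`, `nri_case`, `nri_control`.
#' @examples
#' sc <- risk_scenario("cvd")
#' cs <- combine_scores(score_moments(sc$design, sc$trait, sc$env), sc$env,
#'                      "unweighted")
#' categorical_nri(cs, sc$trait, a = 0.10)
#' @export
categorical_nri <- function(comb, trait, a) {
  stopifnot(inherits(comb, "combined_score"), trait$kind == "binary")
  if (any(a <= 0 | a >= 1)) abort("`a` must lie in (0, 1).")
  K <- trait$K
  tau <- trait$tau
  # identical scores: nothing is reclassified
  if (identical_scores(comb)) {
    return(tibble(a = a, nri_case = 0, nri_control = 0))
  }
  S <- trivariate_joint(comb)
  rows <- lapply(a, function(ai) {
    aX <- score_at_risk(ai, comb$r2_xy, K)
    aS <- score_at_risk(ai, comb$r2_comb, K)
    up_case <- mvn_rectangle(c(tau, -Inf, aS), c(Inf, aX, Inf), S)
    down_case <- mvn_rectangle(c(tau, aX, -Inf), c(Inf, Inf, aS), S)
    down_ctrl <- mvn_rectangle(c(-Inf, aX, -Inf), c(tau, Inf, aS), S)
    up_ctrl <- mvn_rectangle(c(-Inf, -Inf, aS), c(tau, aX, Inf), S)
    c((up_case - down_case) / K, (down_ctrl - up_ctrl) / (1 - K))
  })
  tibble(
    a = a,
    nri_case = vapply(rows, `[`, numeric(1), 1),
    nri_control = vapply(rows, `[`, numeric(1), 2)
  )
}

identical_scores <- function(comb) {
  abs(comb$r2_comb - comb$r2_xy) < 1e-12 &&
    abs(comb$cov_gcomb_x - comb$r2_xy) < 1e-12
}

#' Continuous (category-free) net reclassification improvement
#'
#' In cases, the proportion whose calibrated combined score exceeds the
#' environmental score minus the proportion for which it is lower:
#' `2 * Pr(gamma*S_comb > X | D = 1) - 1`; mirrored in controls. The
#' difference score `gamma*S_comb - X` is normal with variance
#' `r2_comb + r2_xy - 2*cov_gcomb_x` and covariance `r2_comb - r2_xy`
#' with liability, so both components are bivariate-normal orthant
#' probabilities. A degenerate difference (identical scores) returns
#' `(0, 0)` by convention.
#'
#' @inheritParams categorical_nri
#' @return A tibble with columns `cnri_case`, `cnri_control`.
#' @export
continuous_nri <- function(comb, trait) {
  stopifnot(inherits(comb, "combined_score"), trait$kind == "binary")
  K <- trait$K
  tau <- trait$tau
  var_d <- comb$r2_comb + comb$r2_xy - 2 * comb$cov_gcomb_x
  if (var_d <= 1e-14) {
    return(tibble(cnri_case = 0, cnri_control = 0))
  }
  r <- (comb$r2_comb - comb$r2_xy) / sqrt(var_d)
  # P(Y <= tau, Delta <= 0) and P(Y > tau, Delta > 0) from the CDF
  p00 <- pbvn(tau, 0, r)
  p11 <- 1 - pnorm(tau) - 0.5 + p00
  tibble(
    cnri_case = 2 * p11 / K - 1,
    cnri_control = 2 * p00 / (1 - K) - 1
  )
}

#' Integrated discrimination improvement
#'
#' The IDI is the difference, between the calibrated combined score and the
#' environmental score, of the case-control gap in mean absolute risk.
#' For each score the gap is the one-dimensional integral over liability
#' `l` of `pnorm((tau - l)/sqrt(1 - r2))` weighted by the difference of
#' the control and case conditional densities of the score (normal with
#' the [conditional_moments()] parameters), evaluated by adaptive
#' quadrature.
#'
#' @inheritParams categorical_nri
#' @return The IDI as a single number (a risk difference).
#' @export
idi <- function(comb, trait) {
  stopifnot(inherits(comb, "combined_score"), trait$kind == "binary")
  if (identical_scores(comb)) return(0)
  risk_gap(comb$r2_comb, trait) - risk_gap(comb$r2_xy, trait)
}

# mean risk in cases minus mean risk in controls for a calibrated score
risk_gap <- function(r2, trait) {
  if (r2 == 0) return(0)
  K <- trait$K
  tau <- trait$tau
  cm <- conditional_moments(r2, K)
  integrand <- function(l) {
    pnorm((tau - l) / sqrt(1 - r2)) *
      (dnorm(l, cm$mean_control, sqrt(cm$var_control)) -
         dnorm(l, cm$mean_case, sqrt(cm$var_case)))
  }
  res <- integrate(integrand, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)
  if (res$message != "OK") abort("IDI quadrature failed to converge.")
  res$value
}
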