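#' Conditional moments of a calibrated score given disease status
#'
#' Under the liability-threshold model, a calibrated risk score with
#' liability R-squared `r2` is jointly normal with the liability, and its
#' distribution conditional on disease status `D` is approximated as normal
#' with the moments of the liability's truncated distribution scaled
#' through the score-liability regression. With `tau = qnorm(1 - K)`,
#' `z1 = dnorm(tau)/K` and `z0 = dnorm(tau)/(1 - K)`:
#'
#' * `mean_case = z1 * r2`, `var_case = r2 * (1 - r2 * z1 * (z1 - tau))`
#' * `mean_control = -z0 * r2`,
#'   `var_control = r2 * (1 - r2 * z0 * (z0 + tau))`
#'
#' The means obey the law of total expectation
#' (`K * mean_case + (1-K) * mean_control = 0`).
#'
#' @param r2 Liability variance explained by the calibrated score, in
#'   `[0, 1)`. Vectorized.
#' @param K Disease prevalence in `(0, 1)`.
#'
#' @return A tibble with columns `r2`, `mean_case`, `var_case`,
#'   `mean_control`, `var_control`.
#' @export
conditional_moments <- function(r2, K) {
  if (any(r2 < 0 | r2 >= 1)) abort("`r2` must lie in [0, 1).")
  if (!(K > 0 && K < 1)) abort("`K` must lie in (0, 1).")
  tau <- qnorm(1 - K)
  z1 <- dnorm(tau) / K
  z0 <- dnorm(tau) / (1 - K)
  tibble(
    r2 = r2,
    mean_case = z1 * r2,
    var_case = r2 * (1 - r2 * z1 * (z1 - tau)),
    mean_control = -z0 * r2,
    var_control = r2 * (1 - r2 * z0 * (z0 + tau))
  )
}

#' Expected AUC of a score with given liability R-squared
#'
#' Area under the ROC curve as the normal concordance probability of the
#' case and control score distributions:
#' `pnorm((mean_case - mean_control) / sqrt(var_case + var_control))`,
#' using the moments of [conditional_moments()]. An uninformative score
#' (`r2 = 0`) returns exactly 0.5.
#'
#' @inheritParams conditional_moments
#' @return AUC values in `[0.5, 1)`, vectorized over `r2`.
#' @examples
#' liability_auc(0.0375, K = 0.05)  # environmental score, ~0.618
#' @export
liability_auc <- function(r2, K) {
  cm <- conditional_moments(r2, K)
  out <- rep(0.5, length(r2))
  pos <- cm$r2 > 0
  out[pos] <- pnorm(
    (cm$mean_case[pos] - cm$mean_control[pos]) /
      sqrt(cm$var_case[pos] + cm$var_control[pos])
  )
  out
}

#' Proportion of cases captured in the top risk quantile
#'
#' The Lorenz-curve view of risk stratification: among the fraction `q` of
#' the population with the highest values of a calibrated score (variance
#' `r2`), what percentage of all cases is found? The population threshold
#' is `sqrt(r2) * qnorm(1 - q)`, and the captured proportion follows from
#' the conditional case distribution:
#' `100 * (1 - pnorm((sqrt(r2) * qnorm(1 - q) - mean_case) / sd_case))`.
#' An uninformative score captures `100 * q` (random selection); `q = 1`
#' always captures 100%.
#'
#' @inheritParams conditional_moments
#' @param q Population fraction(s) in `(0, 1]`, vectorized.
#' @return Percentages of cases captured.
#' @examples
#' case_capture(0.0375, K = 0.05, q = c(0.1, 0.2, 0.5))
#' @export
case_capture <- function(r2, K, q) {
  if (any(q <= 0 | q > 1)) abort("`q` must lie in (0, 1].")
  stopifnot(length(r2) == 1)
  if (r2 == 0) return(100 * q)
  cm <- conditional_moments(r2, K)
  thr <- sqrt(r2) * qnorm(1 - q)
  100 * (1 - pnorm((thr - cm$mean_case) / sqrt(cm$var_case)))
}

#' Sensitivity and specificity at an absolute-risk threshold
#'
#' Individuals are flagged when their absolute risk under the calibrated
#' score exceeds `a`. The score cutoff with risk exactly `a` is
#' `s* = tau - sqrt(1 - r2) * qnorm(1 - a)` (see [score_at_risk()]);
#' sensitivity is `Pr(score > s* | D = 1)` and specificity
#' `Pr(score <= s* | D = 0)` under the conditional normal approximations.
#'
#' @inheritParams conditional_moments
#' @param a Absolute-risk threshold(s) in `(0, 1)`, vectorized.
#' @return A tibble with columns `a`, `sensitivity`, `specificity`.
#' @export
sens_spec <- function(r2, K, a) {
  if (any(a <= 0 | a >= 1)) abort("`a` must lie in (0, 1).")
  stopifnot(length(r2) == 1)
  if (r2 >= 1) abort("`r2` must be below 1.")
  tau <- qnorm(1 - K)
  cut <- tau - sqrt(1 - r2) * qnorm(1 - a)
  if (r2 == 0) {
    # constant score at 0: everyone (no one) flagged as a < K (a > K)
    flagged <- cut < 0
    return(tibble(
      a = a,
      sensitivity = as.numeric(flagged),
      specificity = as.numeric(!flagged)
    ))
  }
  cm <- conditional_moments(r2, K)
  tibble(
    a = a,
    sensitivity = 1 - pnorm((cut - cm$mean_case) / sqrt(cm$var_case)),
    specificity = pnorm((cut - cm$mean_control) / sqrt(cm$var_control))
  )
}
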