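#' Combine polygenic and environmental scores
#'
#' Forms `S_comb = w1 * S_hat + w2 * X` and its accuracy moments. Schemes:
#'
#' * `"ols"` -- `(w1, w2)` solve the 2x2 normal equations of the regression
#'   of the outcome on both scores, i.e. the Gram matrix
#'   `[[var_s, cov_sx], [cov_sx, r2_xy]]` applied to the right-hand side
#'   `(cov_sy, r2_xy)`. These weights maximize the combined R-squared and
#'   make the calibration coefficient exactly 1.
#' * `"unweighted"` -- the common simple sum, `w1 = w2 = 1`.
#' * `"polygenic"` / `"environment"` -- single-score reductions
#'   `(1, 0)` and `(0, 1)`, so every downstream metric has one code path.
#'
#' Derived quantities: `cov_comb_y = w1*cov_sy + w2*r2_xy`; `var_comb =
#' w1^2*var_s + w2^2*r2_xy + 2*w1*w2*cov_sx`; `r2_comb =
#' cov_comb_y^2 / var_comb`; calibration `gamma = cov_comb_y / var_comb`
#' (regression of liability on the combined score, so the calibrated score
#' `gamma * S_comb` has variance `r2_comb`); and
#' `cov(gamma * S_comb, X) = gamma * (w1*cov_sx + w2*r2_xy)`.
#'
#' A singular Gram matrix (e.g. a degenerate polygenic score) falls back to
#' the environment-only score with a warning.
#'
#' @param moments A [score_moments()].
#' @param env The [env_model()] the moments were computed against.
#' @param scheme Weighting scheme, see Details.
#'
#' @return An object of class `combined_score`: list with `w1`, `w2`,
#'   `scheme`, `cov_comb_y`, `var_comb`, `r2_comb`, `gamma`,
#'   `cov_gcomb_x`, and the environmental variance `r2_xy` carried along
#'   for reclassification.
#' @examples
#' sc <- risk_scenario("cvd")
#' mom <- score_moments(sc$design, sc$trait, sc$env)
#' combine_scores(mom, sc$env, "ols")$gamma  # exactly 1
#' @export
combine_scores <- function(moments, env,
                           scheme = c("ols", "unweighted",
                                      "polygenic", "environment")) {
  stopifnot(inherits(moments, "score_moments"), inherits(env, "env_model"))
  scheme <- match.arg(scheme)
  vs <- moments$var_s
  cx <- moments$cov_sx
  cy <- moments$cov_sy
  rxy <- env$r2_xy

  w <- switch(scheme,
    unweighted = c(1, 1),
    polygenic = c(1, 0),
    environment = c(0, 1),
    ols = {
      det <- vs * rxy - cx^2
      if (!is.finite(det) || det < 1e-12 * max(vs * rxy, 1e-300)) {
        warn("singular score Gram matrix; falling back to environment-only weights.")
        c(0, 1)
      } else {
        # closed-form 2x2 solve (Cramer)
        c((cy * rxy - cx * rxy) / det, (vs * rxy - cx * cy) / det)
      }
    }
  )
  w1 <- w[1]; w2 <- w[2]
  cov_comb_y <- w1 * cy + w2 * rxy
  var_comb <- w1^2 * vs + w2^2 * rxy + 2 * w1 * w2 * cx
  if (var_comb <= 0) {
    abort("combined score has nonpositive variance; inconsistent inputs.")
  }
  r2_comb <- cov_comb_y^2 / var_comb
  gamma <- cov_comb_y / var_comb
  structure(
    list(
      w1 = w1, w2 = w2, scheme = scheme,
      cov_comb_y = cov_comb_y, var_comb = var_comb,
      r2_comb = r2_comb, gamma = gamma,
      cov_gcomb_x = gamma * (w1 * cx + w2 * rxy),
      r2_xy = rxy
    ),
    class = "combined_score"
  )
}

#' @export
print.combined_score <- function(x, ...) {
  cat(sprintf(
    "<combined_score> scheme = %s: w = (%.4g, %.4g), R2 = %.6g, gamma = %.6g\n",
    x$scheme, x$w1, x$w2, x$r2_comb, x$gamma
  ))
  invisible(x)
}
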