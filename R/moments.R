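#' Second-moment tail factor of the standard normal
#'
#' Computes `T(x0, x1) = pnorm(x0) - pnorm(x1) + x1*dnorm(x1) - x0*dnorm(x0)`,
#' the integral of `z^2 * dnorm(z)` over `[x1, x0]`. This factor carries the
#' entire effect of P-value selection on the moments of an estimated
#' polygenic score: evaluated at the shrunken selection quantiles it gives
#' the retained fraction of genetic signal, and at the raw quantiles the
#' retained fraction of estimation noise.
#'
#' Infinite limits are evaluated exactly (`x * dnorm(x) -> 0`), so the open
#' selection window `p0 = 0` incurs no large-argument surrogate.
#'
#' @param x0 Upper limit (may be `Inf`); must satisfy `x0 >= x1`.
#' @param x1 Lower limit. Both arguments are vectorized and recycled.
#'
#' @return Nonnegative numeric vector.
#' @examples
#' truncation_factor(Inf, 0)          # 0.5
#' truncation_factor(Inf, 1.959964)   # mass of z^2 phi(z) beyond 1.96
#' @export
truncation_factor <- function(x0, x1) {
  k <- vctrs_recycle2(x0, x1)
  x0 <- k[[1]]; x1 <- k[[2]]
  if (any(x0 < x1)) {
    abort("invalid selection window: requires x0 >= x1 elementwise.")
  }
  xphi <- function(x) ifelse(is.infinite(x), 0, x * dnorm(x))
  pnorm(x0) - pnorm(x1) + xphi(x1) - xphi(x0)
}

# minimal common-length recycling (base R, no vctrs dependency)
vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(b) != n) b <- rep_len(b, n)
  list(a, b)
}

#' Selection quantiles and their shrinkage under finite training
#'
#' The raw selection quantiles are `qj = qnorm(1 - pj/2)` for the two-sided
#' window P-values; a marker's estimated effect exceeds them when selected.
#' Because true effects are shrunk relative to their estimates, the
#' quantiles that apply to the true-effect distribution are `rj = qj *
#' theta` with shrinkage multiplier
#' `theta = (n * h2_chip / ((1 - pi0) * m) + 1)^(-1/2)` for a continuous
#' outcome. For a binary outcome estimated on the observed case-control
#' scale, `n` is replaced by `n / (P * (1 - P))` and `h2_chip` by
#' `c^2 * h2_chip`, with `c` the observed-to-liability scale factor.
#' The infinite-training limit is taken exactly (`theta = 0`).
#'
#' @param design A [polygenic_design()].
#' @param trait A [trait_model()].
#'
#' @return A list with elements `q0`, `q1`, `r0`, `r1`, `theta`.
#' @export
selection_quantiles <- function(design, trait) {
  stopifnot(inherits(design, "polygenic_design"), inherits(trait, "trait_model"))
  q0 <- if (design$p0 == 0) Inf else qnorm(1 - design$p0 / 2)
  q1 <- qnorm(1 - design$p1 / 2)
  if (is.infinite(design$n)) {
    theta <- 0
  } else if (trait$kind == "continuous") {
    theta <- 1 / sqrt(
      design$n * design$h2_chip / ((1 - design$pi0) * design$m) + 1
    )
  } else {
    nu <- design$n / (trait$P * (1 - trait$P))
    theta <- 1 / sqrt(
      nu * trait$c^2 * design$h2_chip / ((1 - design$pi0) * design$m) + 1
    )
  }
  r0 <- if (is.infinite(q0)) Inf else q0 * theta
  r1 <- if (is.infinite(q1)) Inf else q1 * theta
  list(q0 = q0, q1 = q1, r0 = r0, r1 = r1, theta = theta)
}

#' Moments of the estimated polygenic score
#'
#' Expected covariance of the estimated polygenic score with the (liability
#' scale) outcome, its expected variance, and its covariance with the
#' environmental score, under finite training with P-value selection.
#' Writing `T()` for [truncation_factor()], `Tr = T(r0, r1)` at the
#' shrunken quantiles and `Tq = T(q0, q1)` at the raw quantiles:
#'
#' * `cov_sy = 2 * h2 * Tr`
#' * continuous `var_s = 2*m*pi0/n * Tq +
#'     2*m*(1-pi0) * (h2/((1-pi0)*m) + 1/n) * Tr`
#' * `cov_sx = 2 * rho * sqrt(h2 * r2_xy * r2_gx) * Tr`
#'
#' For a binary outcome the estimation noise lives on the observed scale and
#' is back-transformed by `1/c`, giving
#' `var_s = (2*m*pi0*P*(1-P)/n) * Tq / c^2 +
#'  (2*m/c^2) * (1-pi0) * (c^2*h2/((1-pi0)*m) + P*(1-P)/n) * Tr`,
#' with the binary shrinkage entering `r0, r1` (see
#' [selection_quantiles()]). All binary moments are returned on the
#' liability scale. The `n = Inf` path evaluates the exact limit:
#' `cov_sy = var_s = h2 * 2 * Tr`, so the score R-squared attains the chip
#' heritability when the window is fully open.
#'
#' @inheritParams selection_quantiles
#' @param env An [env_model()].
#'
#' @return An object of class `score_moments`: list with `cov_sy`, `var_s`,
#'   `cov_sx`, the truncation factors `tfac_signal` and `tfac_null`, the
#'   selection quantiles, and a `degenerate` flag set when no variance is
#'   expected to pass the window.
#' @examples
#' d <- polygenic_design(n = Inf, m = 1000, p1 = 1, pi0 = 0.5, h2_chip = 0.3)
#' m <- score_moments(d, trait_model("continuous"), env_model(0, 0, 0))
#' m$cov_sy / m$var_s  # = 1: complete noiseless score
#' @export
score_moments <- function(design, trait, env) {
  stopifnot(inherits(env, "env_model"))
  sq <- selection_quantiles(design, trait)
  Tr <- truncation_factor(sq$r0, sq$r1)
  Tq <- truncation_factor(sq$q0, sq$q1)
  h2 <- design$h2_chip
  m <- design$m
  pi0 <- design$pi0
  n <- design$n

  cov_sy <- 2 * h2 * Tr
  if (is.infinite(n)) {
    var_s <- 2 * h2 * Tr
  } else if (trait$kind == "continuous") {
    var_s <- 2 * m * pi0 / n * Tq +
      2 * m * (1 - pi0) * (h2 / ((1 - pi0) * m) + 1 / n) * Tr
  } else {
    pq <- trait$P * (1 - trait$P)
    var_s <- 2 * m * pi0 * pq / n * Tq / trait$c^2 +
      2 * m / trait$c^2 * (1 - pi0) *
        (trait$c^2 * h2 / ((1 - pi0) * m) + pq / n) * Tr
  }
  cov_sx <- 2 * env$rho * sqrt(h2 * env$r2_xy * env$r2_gx) * Tr

  degenerate <- var_s <= .Machine$double.eps
  if (degenerate) {
    warn("no marker variance expected to pass the selection window; polygenic score is degenerate.")
  }
  structure(
    list(
      cov_sy = cov_sy, var_s = var_s, cov_sx = cov_sx,
      tfac_signal = Tr, tfac_null = Tq, quantiles = sq,
      degenerate = degenerate,
      h2_chip = h2
    ),
    class = "score_moments"
  )
}

#' @export
print.score_moments <- function(x, ...) {
  cat(sprintf(
    "<score_moments> cov(S,Y) = %.6g, var(S) = %.6g, cov(S,X) = %.6g  (R2 = %.6g)\n",
    x$cov_sy, x$var_s, x$cov_sx,
    if (x$var_s > 0) x$cov_sy^2 / x$var_s else 0
  ))
  invisible(x)
}
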