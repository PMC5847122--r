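#' Training design and genetic architecture of the outcome
#'
#' Describes a GWAS training study and the polygenic architecture assumed for
#' the outcome: `n` subjects are used to estimate marginal effects of `m`
#' independent standardized markers, of which a proportion `pi0` are null;
#' the non-null effects are normal with total variance `h2_chip` (the chip
#' heritability of the standardized outcome). Markers enter the polygenic
#' score when their two-sided training P-value lies in the window
#' `(p0, p1]`; the conventional "select by P < x" corresponds to
#' `p0 = 0, p1 = x`.
#'
#' @param n Training sample size (positive; `Inf` requests the exact
#'   infinite-training-sample limit rather than a large-`n` surrogate).
#' @param m Number of independent markers on the panel (positive integer).
#' @param p0,p1 Lower and upper two-sided P-values of the selection window;
#'   `0 <= p0 < p1 <= 1`. `p0 = 0` maps to an infinite upper selection
#'   quantile.
#' @param pi0 Proportion of markers with no effect on the outcome, in
#'   `[0, 1)`.
#' @param h2_chip Chip heritability of the outcome, in `(0, 1]`.
#'
#' @return An object of class `polygenic_design`.
#' @seealso [trait_model()], [env_model()], [risk_scenario()]
#' @examples
#' polygenic_design(n = 2000, m = 1000, p1 = 0.05, pi0 = 0.9, h2_chip = 0.3)
#' @export
polygenic_design <- function(n, m, p0 = 0, p1 = 1, pi0, h2_chip) {
  stopifnot(length(n) == 1, length(m) == 1, length(p0) == 1, length(p1) == 1)
  if (!(is.numeric(n) && n > 0)) {
    abort("`n` must be a positive number (possibly Inf).")
  }
  if (is.finite(n) && n != round(n)) {
    abort("`n` must be a whole number of training subjects.")
  }
  if (!(is.numeric(m) && is.finite(m) && m > 0 && m == round(m))) {
    abort("`m` must be a positive integer number of markers.")
  }
  if (!(p0 >= 0 && p0 < 1)) abort("`p0` must lie in [0, 1).")
  if (!(p1 > 0 && p1 <= 1)) abort("`p1` must lie in (0, 1].")
  if (!(p0 < p1)) abort("selection window requires p0 < p1.")
  if (!(pi0 >= 0 && pi0 < 1)) {
    abort("`pi0` must lie in [0, 1): at least some markers carry signal.")
  }
  if (!(h2_chip > 0 && h2_chip <= 1)) abort("`h2_chip` must lie in (0, 1].")
  structure(
    list(n = n, m = m, p0 = p0, p1 = p1, pi0 = pi0, h2_chip = h2_chip),
    class = "polygenic_design"
  )
}

#' Outcome scale: continuous trait or liability-threshold disease
#'
#' A continuous outcome is taken as standardized. A binary outcome follows
#' the liability-threshold model: disease occurs when a standard-normal
#' latent liability exceeds `tau = qnorm(1 - K)`, `K` the population
#' prevalence. When effects are estimated from a case-control training
#' sample with case fraction `P` (equal to `K` in a prospective design),
#' effects on the observed 0/1 scale relate to effects on the liability
#' scale by the factor `c = dnorm(tau) * P * (1 - P) / (K * (1 - K))`.
#' `tau` and `c` are always derived from `K` and `P` at construction.
#'
#' @param kind `"continuous"` or `"binary"`.
#' @param K Prevalence in `(0, 1)` (binary only).
#' @param P Case fraction of the training sample in `(0, 1)` (binary only;
#'   defaults to `K`).
#'
#' @return An object of class `trait_model`. Binary traits carry derived
#'   fields `tau` and `c`.
#' @examples
#' trait_model("binary", K = 0.15, P = 0.33)
#' @export
trait_model <- function(kind = c("continuous", "binary"), K = NULL, P = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (!is.null(K) || !is.null(P)) {
      abort("a continuous trait has no prevalence or sampling fraction.")
    }
    return(structure(list(kind = "continuous"), class = "trait_model"))
  }
  if (is.null(K) || !(K > 0 && K < 1)) abort("binary trait needs K in (0, 1).")
  if (is.null(P)) P <- K
  if (!(P > 0 && P < 1)) abort("`P` must lie in (0, 1).")
  tau <- qnorm(1 - K)
  cc <- dnorm(tau) * P * (1 - P) / (K * (1 - K))
  structure(
    list(kind = "binary", K = K, P = P, tau = tau, c = cc),
    class = "trait_model"
  )
}

#' Environmental risk score model
#'
#' The environmental (more generally, nongenetic) score `X` has a known unit
#' effect on the standardized outcome, so the variance it explains equals its
#' own variance `r2_xy`. `X` may itself be heritable with chip heritability
#' `r2_gx`, and its marker effects correlate with those on the outcome with
#' genetic (chip) correlation `rho`; the chip covariance between the full
#' polygenic score and `X` is then `rho * sqrt(h2_chip * r2_xy * r2_gx)`.
#'
#' @param r2_xy Variance in the outcome explained by `X`, in `[0, 1)`.
#' @param r2_gx Chip heritability of `X`, in `[0, 1]`.
#' @param rho Genetic (chip) correlation between `X` and the outcome, in
#'   `[-1, 1]`.
#'
#' @return An object of class `env_model`.
#' @examples
#' env_model(r2_xy = 0.052, r2_gx = 0.3, rho = 0.1)
#' @export
env_model <- function(r2_xy, r2_gx, rho) {
  if (!(r2_xy >= 0 && r2_xy < 1)) abort("`r2_xy` must lie in [0, 1).")
  if (!(r2_gx >= 0 && r2_gx <= 1)) abort("`r2_gx` must lie in [0, 1].")
  if (!(rho >= -1 && rho <= 1)) abort("`rho` must lie in [-1, 1].")
  # implied corr(S, X) = rho * sqrt(r2_gx), always a valid correlation here,
  # but guard against degenerate rounding from callers
  if (abs(rho) * sqrt(r2_gx) > 1 + 1e-12) {
    abort("implied correlation between polygenic score and X exceeds 1.")
  }
  structure(
    list(r2_xy = r2_xy, r2_gx = r2_gx, rho = rho),
    class = "env_model"
  )
}

#' @export
print.polygenic_design <- function(x, ...) {
  cat(
    "<polygenic_design> n =", format(x$n, big.mark = ","),
    " m =", format(x$m, big.mark = ","),
    sprintf(" window (%g, %g]", x$p0, x$p1),
    " pi0 =", x$pi0, " h2_chip =", x$h2_chip, "\n"
  )
  invisible(x)
}

#' @export
print.trait_model <- function(x, ...) {
  if (x$kind == "continuous") {
    cat("<trait_model> continuous (standardized)\n")
  } else {
    cat(sprintf(
      "<trait_model> binary: K = %g, P = %g, tau = %.4f, c = %.4f\n",
      x$K, x$P, x$tau, x$c
    ))
  }
  invisible(x)
}

#' @export
print.env_model <- function(x, ...) {
  cat(sprintf(
    "<env_model> r2_xy = %g, r2_gx = %g, rho = %g\n",
    x$r2_xy, x$r2_gx, x$rho
  ))
  invisible(x)
}

# -------------------------------------------------------------------------
# Published worked scenarios

#' Preset worked scenarios
#'
#' Fully parameterized scenarios for three well-studied settings:
#'
#' * `"cvd"` -- coronary heart disease trained on 63,746 cases and 130,681
#'   controls (2.05 controls per case): `m` = 100,000 independent SNPs,
#'   chip heritability 0.3, `pi0` = 0.8, prevalence 0.15, environmental
#'   score variance 0.052 with chip heritability 0.3.
#' * `"breast_cancer"` -- 33,673 cases and 33,381 controls (0.99 controls
#'   per case): `m` = 100,000, chip heritability 0.3, `pi0` = 0.95,
#'   prevalence 0.05, environmental score variance 0.0375.
#' * `"height"` -- continuous trait with `m` = 2.5 million markers, chip
#'   heritability 0.48, `pi0` = 0.995; the "environmental" score is the
#'   mean-parental value (family history) derived by
#'   [family_history_params()] from total heritability 0.8.
#'
#' `K`, `pi0`, `rho` and `r2_gx` may be overridden to explore sensitivity
#' variants (e.g. CVD at prevalence 0.06, or null proportion 0.95).
#'
#' @param name One of `"cvd"`, `"breast_cancer"`, `"height"`.
#' @param rho Genetic correlation override (defaults: 0.1 for the disease
#'   scenarios; `1/sqrt(2)` is fixed for height).
#' @param r2_gx Chip heritability of the environmental score (defaults: 0.3
#'   for CVD, 0.1 for breast cancer; derived for height).
#' @param K,pi0 Optional overrides of prevalence and null-marker proportion.
#' @param p1 Upper selection P-value (default `5e-8`, genome-wide
#'   significance).
#' @param n Optional override of the total training sample size (`Inf`
#'   allowed). Defaults to the scenario's published case/control counts,
#'   or 301,000 subjects for height.
#'
#' @return An object of class `risk_scenario`: a list with elements
#'   `design`, `trait`, `env`, `name` and `controls_per_case`.
#' @examples
#' sc <- risk_scenario("cvd", rho = 0.4)
#' sc$trait
#' @export
risk_scenario <- function(name = c("cvd", "breast_cancer", "height"),
                          rho = NULL, r2_gx = NULL, K = NULL, pi0 = NULL,
                          p1 = 5e-8, n = NULL) {
  name <- match.arg(name)
  out <- switch(name,
    cvd = {
      cases <- 63746; controls <- 130681
      ntot <- if (is.null(n)) cases + controls else n
      P <- cases / (cases + controls)
      list(
        design = polygenic_design(
          n = ntot, m = 1e5, p1 = p1,
          pi0 = pi0 %||% 0.8, h2_chip = 0.3
        ),
        trait = trait_model("binary", K = K %||% 0.15, P = P),
        env = env_model(
          r2_xy = 0.052, r2_gx = r2_gx %||% 0.3,
          rho = rho %||% 0.1
        ),
        controls_per_case = controls / cases
      )
    },
    breast_cancer = {
      cases <- 33673; controls <- 33381
      ntot <- if (is.null(n)) cases + controls else n
      P <- cases / (cases + controls)
      list(
        design = polygenic_design(
          n = ntot, m = 1e5, p1 = p1,
          pi0 = pi0 %||% 0.95, h2_chip = 0.3
        ),
        trait = trait_model("binary", K = K %||% 0.05, P = P),
        env = env_model(
          r2_xy = 0.0375, r2_gx = r2_gx %||% 0.1,
          rho = rho %||% 0.1
        ),
        controls_per_case = controls / cases
      )
    },
    height = {
      h2 <- 0.8; h2_chip <- 0.48
      list(
        design = polygenic_design(
          n = n %||% 301000, m = 2.5e6, p1 = p1,
          pi0 = pi0 %||% 0.995, h2_chip = h2_chip
        ),
        trait = trait_model("continuous"),
        env = family_history_params(h2 = h2, h2_chip = h2_chip),
        controls_per_case = NA_real_
      )
    }
  )
  out$name <- name
  structure(out, class = "risk_scenario")
}

#' @export
print.risk_scenario <- function(x, ...) {
  cat("<risk_scenario>", x$name, "\n")
  print(x$design); print(x$trait); print(x$env)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
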