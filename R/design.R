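#' Optimal P-value selection threshold
#'
#' Maximizes a chosen accuracy objective over the upper selection P-value
#' `p1` (with `p0` fixed at 0), on a 200-point log-spaced grid over
#' `[1e-10, 1]` followed by golden-section refinement in `log(p1)` to a
#' relative tolerance of `1e-3`. Ties break toward smaller `p1`.
#'
#' @param design A [polygenic_design()]; its `p1` is the quantity being
#'   optimized and is ignored on input.
#' @param trait A [trait_model()].
#' @param env An [env_model()].
#' @param scheme Combination scheme passed to [combine_scores()].
#' @param objective One of `"auc"`, `"r2"`, `"nri_case"`, `"nri_control"`,
#'   `"cnri_case"`, `"cnri_control"`, `"idi"`. `"r2"` is the only
#'   objective available for continuous traits.
#' @param a Absolute-risk threshold, required for the NRI objectives.
#'
#' @return A one-row tibble: `objective`, `p1_opt`, `value`.
#' @examples
#' sc <- risk_scenario("cvd")
#' optimize_threshold(sc$design, sc$trait, sc$env, "unweighted", "auc")
#' @export
optimize_threshold <- function(design, trait, env,
                               scheme = "ols",
                               objective = c("auc", "r2", "nri_case",
                                             "nri_control", "cnri_case",
                                             "cnri_control", "idi"),
                               a = 0.1) {
  objective <- match.arg(objective)
  f <- objective_fn(design, trait, env, scheme, objective, a)
  lgrid <- seq(-10, 0, length.out = 200)
  vals <- vapply(lgrid, f, numeric(1))
  if (max(vals) - min(vals) < 1e-14) {
    warn("objective is flat over the selection threshold; returning the boundary.")
    return(tibble(objective = objective, p1_opt = 1, value = f(0)))
  }
  i <- which.max(vals) # first max: ties toward smaller p1
  lo <- lgrid[max(1, i - 1)]
  hi <- lgrid[min(length(lgrid), i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)
  tibble(
    objective = objective,
    p1_opt = 10^opt$maximum,
    value = opt$objective
  )
}

# objective as a function of log10(p1)
objective_fn <- function(design, trait, env, scheme, objective, a) {
  if (trait$kind == "continuous" && objective != "r2") {
    abort("continuous traits support only the `r2` objective.")
  }
  function(lp1) {
    d <- design
    d$p0 <- 0
    d$p1 <- 10^lp1
    mom <- suppressWarnings(score_moments(d, trait, env))
    cs <- suppressWarnings(combine_scores(mom, env, scheme))
    switch(objective,
      r2 = cs$r2_comb,
      auc = liability_auc(cs$r2_comb, trait$K),
      nri_case = categorical_nri(cs, trait, a)$nri_case,
      nri_control = categorical_nri(cs, trait, a)$nri_control,
      cnri_case = continuous_nri(cs, trait)$cnri_case,
      cnri_control = continuous_nri(cs, trait)$cnri_control,
      idi = idi(cs, trait)
    )
  }
}

#' Training sample size required to reach a target accuracy
#'
#' Finds the smallest training sample size (reported to 3 significant
#' figures) at which the chosen objective reaches `target`. The objective
#' is first evaluated on the exact infinite-training path; an unreachable
#' target raises an error naming that asymptotic limit. The search then
#' bisects on `log10(n)`; when `optimize_p1 = TRUE` (the default) the
#' objective is maximized over the selection threshold at each `n` via
#' [optimize_threshold()].
#'
#' For binary designs the result is also expressed as a number of cases,
#' `n * P`, the convention used when quoting case-control consortium
#' sizes at a fixed controls-per-case ratio.
#'
#' @inheritParams optimize_threshold
#' @param target Required objective value.
#' @param optimize_p1 Maximize over `p1` at each `n`? If `FALSE`, the
#'   design's own `p1` is used throughout.
#'
#' @return A one-row tibble: `objective`, `target`, `n` (total subjects),
#'   `n_cases` (binary traits; `NA` otherwise), `p1`, `value` (objective
#'   attained at the returned `n`).
#' @examples
#' \donttest{
#' sc <- risk_scenario("cvd")
#' required_sample_size(sc$design, sc$trait, sc$env, "ols", "auc", 0.75)
#' }
#' @export
required_sample_size <- function(design, trait, env, scheme = "ols",
                                 objective = "auc", target,
                                 optimize_p1 = TRUE, a = 0.1) {
  eval_at <- function(n) {
    d <- design
    d$n <- n
    if (is.infinite(n)) {
      # all windows coincide in the exact limit: no threshold search needed
      p1 <- if (optimize_p1) 1 else design$p1
      return(objective_fn(d, trait, env, scheme, objective, a)(log10(p1)))
    }
    if (optimize_p1) {
      optimize_threshold(d, trait, env, scheme, objective, a)$value
    } else {
      objective_fn(d, trait, env, scheme, objective, a)(log10(design$p1))
    }
  }
  limit <- eval_at(Inf)
  if (target > limit) {
    abort(sprintf(
      "target %g exceeds the asymptotic (infinite-training) limit %g of the %s objective.",
      target, limit, objective
    ))
  }
  lo <- 2; hi <- 9
  while (eval_at(10^hi) < target && hi < 12) hi <- hi + 1
  root <- uniroot(
    function(l) eval_at(10^l) - target,
    lower = lo, upper = hi, tol = 1e-5
  )$root
  n <- signif(10^root, 3)
  val <- eval_at(n)
  if (val < target) { # 3-significant-figure rounding must not undershoot
    step <- 10^(floor(log10(n)) - 2)
    while (eval_at(n) < target) n <- n + step
    val <- eval_at(n)
  }
  p1_used <- if (optimize_p1) {
    d <- design; d$n <- n
    optimize_threshold(d, trait, env, scheme, objective, a)$p1_opt
  } else design$p1
  tibble(
    objective = objective, target = target,
    n = n,
    n_cases = if (trait$kind == "binary") n * trait$P else NA_real_,
    p1 = p1_used, value = val
  )
}

#' Family-history parameterization for a heritable trait
#'
#' Treats the mean-parental value (family history) as the environmental
#' score for a trait with total narrow-sense heritability `h2` and chip
#' heritability `h2_chip`, assuming no shared environment. Under the
#' additive model the genetic covariance between offspring and
#' mean-parents is `h2 / 2`, the variance in offspring explained by the
#' mean-parents is twice the square of that covariance
#' (`r2_xy = h2^2 / 2`), and the genetic correlation is `1 / sqrt(2)`
#' (the mid-parent-offspring value). Rescaling the mean-parent phenotype
#' to have a unit effect on the offspring leaves variance *proportions*
#' unchanged, so the chip heritability of the family-history score is the
#' trait's own chip heritability, `r2_gx = h2_chip`; the implied chip
#' covariance between the full polygenic score and the score is then
#' `rho * sqrt(h2_chip * r2_xy * r2_gx) = h2 * h2_chip / 2` -- the
#' genotyped half-heritability covariance carried through the unit-effect
#' scaling `h2`. A trio simulation (parent genotype pairs, Mendelian
#' segregation, offspring chip scores) confirms these moments; see the
#' methods vignette.
#'
#' @param h2 Total heritability, with `0 < h2_chip <= h2 <= 1`.
#' @param h2_chip Chip heritability of the trait.
#' @return An [env_model()] describing the family-history score.
#' @examples
#' family_history_params(h2 = 0.8, h2_chip = 0.48)  # r2_xy = 0.32
#' @export
family_history_params <- function(h2, h2_chip) {
  if (!(h2 >= 0 && h2 <= 1)) abort("`h2` must lie in [0, 1].")
  if (h2 == 0) return(env_model(0, 0, 0))
  if (!(h2_chip > 0 && h2_chip <= h2)) {
    abort("requires 0 < h2_chip <= h2.")
  }
  env_model(r2_xy = h2^2 / 2, r2_gx = h2_chip, rho = 1 / sqrt(2))
}
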