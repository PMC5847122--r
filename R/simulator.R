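#' Configuration of the individual-level Monte-Carlo simulator
#'
#' Bundles a design, trait and environmental model with the evaluation
#' cohort size, replicate count, and a mandatory seed (no hidden global
#' RNG state: every simulator entry point that consumes a config seeds
#' from it deterministically).
#'
#' @param design A [polygenic_design()] (finite `n`).
#' @param trait A [trait_model()].
#' @param env An [env_model()].
#' @param n_target Evaluation cohort size (positive integer).
#' @param n_reps Number of independent replicates.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(design, trait, env, n_target = 2000, n_reps = 100,
                       seed) {
  stopifnot(
    inherits(design, "polygenic_design"), is.finite(design$n),
    inherits(trait, "trait_model"), inherits(env, "env_model"),
    n_target > 0, n_reps > 0
  )
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  structure(
    list(
      design = design, trait = trait, env = env,
      n_target = as.integer(n_target), n_reps = as.integer(n_reps),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw per-marker effects on outcome and environmental score
#'
#' Marker effects on the outcome follow the normal-null mixture: each of
#' the `m` markers is null with probability `pi0`, otherwise its effect is
#' `N(0, h2_chip / ((1 - pi0) * m))`. Effects on the environmental score
#' share the null set and are built as `alpha = u * beta + v * zeta` on
#' the non-null markers, with independent `zeta` of the same variance and
#' `u = rho * sqrt(r2_xy * r2_gx / h2_chip)`,
#' `v = sqrt((1 - rho^2) * r2_xy * r2_gx / h2_chip)`, so that in
#' expectation `sum(alpha^2) = r2_xy * r2_gx`,
#' `sum(alpha * beta) = rho * sqrt(h2_chip * r2_xy * r2_gx)` and
#' `cor(alpha, beta) = rho` among non-null markers. At `rho = 1` with
#' `r2_xy * r2_gx = h2_chip` this reduces to `alpha = beta`.
#'
#' Consumes the current RNG stream; seed via the wrapper
#' [simulate_replicates()] or `set.seed()`.
#'
#' @param config A [sim_config()].
#' @return A list with numeric vectors `beta` and `alpha` of length `m`.
#' @export
draw_effects <- function(config) {
  d <- config$design; e <- config$env
  m <- d$m
  nonnull <- rbinom(m, 1, 1 - d$pi0) == 1
  sigma2 <- d$h2_chip / ((1 - d$pi0) * m)
  beta <- numeric(m)
  beta[nonnull] <- rnorm(sum(nonnull), 0, sqrt(sigma2))
  ratio <- e$r2_xy * e$r2_gx / d$h2_chip
  u <- e$rho * sqrt(ratio)
  v <- sqrt(pmax(0, (1 - e$rho^2) * ratio))
  alpha <- numeric(m)
  alpha[nonnull] <- u * beta[nonnull] +
    v * rnorm(sum(nonnull), 0, sqrt(sigma2))
  list(beta = beta, alpha = alpha)
}

#' Simulate marginal GWAS estimation and P-value selection
#'
#' For independent standardized markers, per-marker marginal OLS estimates
#' are the true effects plus analytic sampling noise: `N(0, 1/n)` on a
#' continuous outcome, or `N(0, P*(1-P)/n)` on the observed 0/1 scale for
#' a binary outcome whose liability effects are first scaled by `c`
#' (this replaces explicit regression on simulated training genotypes,
#' exactly, and keeps the oracle at desk scale; case-control ascertainment
#' enters through the observed-scale noise variance). Two-sided P-values
#' from the marginal Wald test select markers with `p0 < P <= p1`; binary
#' weights are back-transformed to the liability scale by `1/c`.
#'
#' @inheritParams draw_effects
#' @param effects Output of [draw_effects()].
#' @return Numeric vector of length `m` of score weights on the liability
#'   scale (zero for unselected markers).
#' @export
simulate_training <- function(config, effects) {
  d <- config$design; tr <- config$trait
  if (tr$kind == "continuous") {
    se <- sqrt(1 / d$n)
    bhat <- effects$beta + rnorm(d$m, 0, se)
    back <- 1
  } else {
    se <- sqrt(tr$P * (1 - tr$P) / d$n)
    bhat <- tr$c * effects$beta + rnorm(d$m, 0, se)
    back <- 1 / tr$c
  }
  pval <- 2 * pnorm(-abs(bhat) / se)
  # p0 = 0 is the open lower bound of the window and admits underflowed
  # p-values, matching the infinite-quantile limit of the analytic moments
  keep <- (if (d$p0 == 0) rep(TRUE, d$m) else pval > d$p0) & pval <= d$p1
  ifelse(keep, bhat * back, 0)
}

#' Simulate an evaluation cohort
#'
#' Generates `n_target` individuals under the mediation structure that
#' reproduces the model's moments exactly: standardized independent
#' Gaussian genotypes `G`; environmental score `X = alpha'G + eta` with
#' `var(eta) = r2_xy * (1 - r2_gx)`; outcome
#' `Y = beta'G + b * eta + epsilon`, where the nongenetic component of
#' `X` enters with the coefficient
#' `b = (r2_xy - cov(S, X)) / var(eta)` required for `cov(X, Y) = r2_xy`
#' (unit marginal effect of `X`; the genetic part of `X` is shared with
#' `beta'G`, not double-counted), and `var(epsilon)` tops `var(Y)` up to
#' 1. A negative residual variance means the requested moment combination
#' is infeasible and raises an error. Binary outcomes threshold `Y` at
#' `tau`; evaluation cohorts are population samples.
#'
#' @inheritParams simulate_training
#' @param weights Score weights from [simulate_training()].
#' @return A tibble with columns `s_hat` (estimated polygenic score on the
#'   liability scale), `x`, `y`, and `d` (binary traits only).
#' @export
simulate_cohort <- function(config, effects, weights) {
  d <- config$design; e <- config$env; tr <- config$trait
  n <- config$n_target
  var_eta <- e$r2_xy * (1 - e$r2_gx)
  cov_sx_full <- e$rho * sqrt(d$h2_chip * e$r2_xy * e$r2_gx)
  if (var_eta > 0) {
    b <- (e$r2_xy - cov_sx_full) / var_eta
  } else {
    if (abs(e$r2_xy - cov_sx_full) > 1e-12) {
      abort("infeasible moments: fully heritable X cannot have cov(X,Y) = var(X) unless the chip covariance supplies it.")
    }
    b <- 0
  }
  var_eps <- 1 - d$h2_chip - b^2 * var_eta
  if (var_eps < -1e-12) {
    abort("infeasible moment combination: negative residual outcome variance.")
  }
  var_eps <- max(var_eps, 0)
  G <- matrix(rnorm(n * d$m), n, d$m)
  eta <- rnorm(n, 0, sqrt(var_eta))
  x <- drop(G %*% effects$alpha) + eta
  y <- drop(G %*% effects$beta) + b * eta + rnorm(n, 0, sqrt(var_eps))
  out <- tibble(s_hat = drop(G %*% weights), x = x, y = y)
  if (tr$kind == "binary") out$d <- as.integer(y > tr$tau)
  out
}

#' Empirical accuracy metrics from a simulated cohort
#'
#' Direct counting/averaging counterparts of the analytic metrics, for a
#' cohort carrying a new (calibrated) score in `score`, optionally a
#' comparator score in `old`, and case status `d`. AUC is the empirical
#' concordance probability (rank statistic); capture is the observed case
#' fraction in the top `q` of `score`; NRI components count category moves
#' across the risk threshold(s) `a` with risks mapped through
#' [risk_from_score()] at each score's empirical variance; the IDI
#' averages the individual risk changes.
#'
#' @param cohort A data frame with columns `score`, `d`, and (for
#'   reclassification metrics) `old`.
#' @param trait A binary [trait_model()].
#' @param a Risk threshold(s) for categorical NRI (may be empty).
#' @param q Population fraction(s) for case capture (may be empty).
#' @return A tibble with columns `metric`, `threshold`, `value`.
#' @export
empirical_metrics <- function(cohort, trait, a = numeric(0), q = numeric(0)) {
  stopifnot(all(c("score", "d") %in% names(cohort)))
  d <- cohort$d
  if (!any(d == 1) || !any(d == 0)) abort("cohort needs both cases and controls.")
  s <- cohort$score
  out <- list(tibble(metric = "auc", threshold = NA_real_, value = auc_rank(s, d)))
  for (qq in q) {
    cut <- stats::quantile(s, 1 - qq, type = 8)
    out <- c(out, list(tibble(
      metric = "capture", threshold = qq,
      value = 100 * mean(s[d == 1] > cut)
    )))
  }
  if ("old" %in% names(cohort)) {
    o <- cohort$old
    rs <- risk_from_score(s, min(var(s), 1 - 1e-9), trait$K)
    ro <- risk_from_score(o, min(var(o), 1 - 1e-9), trait$K)
    for (ai in a) {
      up <- rs > ai & ro <= ai
      down <- rs <= ai & ro > ai
      out <- c(out, list(
        tibble(
          metric = "nri_case", threshold = ai,
          value = mean(up[d == 1]) - mean(down[d == 1])
        ),
        tibble(
          metric = "nri_control", threshold = ai,
          value = mean(down[d == 0]) - mean(up[d == 0])
        )
      ))
    }
    out <- c(out, list(
      tibble(
        metric = "cnri_case", threshold = NA_real_,
        value = mean(s[d == 1] > o[d == 1]) - mean(s[d == 1] <= o[d == 1])
      ),
      tibble(
        metric = "cnri_control", threshold = NA_real_,
        value = mean(s[d == 0] <= o[d == 0]) - mean(s[d == 0] > o[d == 0])
      ),
      tibble(
        metric = "idi", threshold = NA_real_,
        value = (mean(rs[d == 1]) - mean(rs[d == 0])) -
          (mean(ro[d == 1]) - mean(ro[d == 0]))
      )
    ))
  }
  dplyr::bind_rows(out)
}

# empirical concordance AUC via the rank (Mann-Whitney) statistic
auc_rank <- function(score, d) {
  r <- rank(score)
  n1 <- sum(d == 1); n0 <- sum(d == 0)
  (sum(r[d == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Replicate the full pipeline and collect empirical summaries
#'
#' Runs `n_reps` independent replicates of effect drawing, marginal GWAS
#' estimation with selection, and cohort generation, and returns one row
#' per replicate with empirical moments of the estimated polygenic score
#' (`cov_sy`, `var_s`, `cov_sx`, all on the liability scale), cohort
#' moment checks (`var_y`, `cov_xy`, `prevalence`), and, for binary
#' traits, empirical metrics of the calibrated combined score against the
#' environmental score (`auc`, `nri_case`/`nri_control` at `a`,
#' `cnri_case`, `cnri_control`, `idi`, `capture` at `q`). The combined
#' score uses the analytic weights and calibration of the matching
#' [combine_scores()] call, which is what the replicates are validating.
#'
#' Fully deterministic given `config$seed`.
#'
#' @inheritParams draw_effects
#' @param scheme Combination scheme for the metric columns.
#' @param a Risk threshold for categorical NRI.
#' @param q Population fraction for capture.
#' @return A tibble with one row per replicate.
#' @export
simulate_replicates <- function(config, scheme = "ols", a = 0.1, q = 0.2) {
  set.seed(config$seed)
  mom <- suppressWarnings(score_moments(config$design, config$trait, config$env))
  cs <- suppressWarnings(combine_scores(mom, config$env, scheme))
  rows <- lapply(seq_len(config$n_reps), function(rep) {
    eff <- draw_effects(config)
    w <- simulate_training(config, eff)
    coh <- simulate_cohort(config, eff, w)
    row <- tibble(
      rep = rep,
      cov_sy = cov(coh$s_hat, coh$y),
      var_s = var(coh$s_hat),
      cov_sx = cov(coh$s_hat, coh$x),
      var_y = var(coh$y),
      cov_xy = cov(coh$x, coh$y)
    )
    if (config$trait$kind == "binary") {
      row$prevalence <- mean(coh$d)
      comb <- cs$gamma * (cs$w1 * coh$s_hat + cs$w2 * coh$x)
      em <- empirical_metrics(
        tibble(score = comb, old = coh$x, d = coh$d),
        config$trait, a = a, q = q
      )
      vals <- setNames(em$value, paste0(
        em$metric, ifelse(is.na(em$threshold), "", "")
      ))
      row <- dplyr::bind_cols(row, as_tibble(as.list(vals)))
    }
    row
  })
  dplyr::bind_rows(rows)
}
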