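#' Project the accuracy of a risk score configuration
#'
#' One-stop evaluation: computes score moments, forms the combined score
#' under the requested scheme, and assembles the accuracy report --
#' R-squared, AUC, categorical NRI and sensitivity/specificity at each
#' risk threshold, continuous NRI, IDI, and case capture at each
#' population quantile. Reclassification metrics compare the calibrated
#' combined score against the environmental score and are reported as `NA`
#' for continuous traits.
#'
#' @param design A [polygenic_design()].
#' @param trait A [trait_model()].
#' @param env An [env_model()].
#' @param scheme Combination scheme, see [combine_scores()].
#' @param risk_thresholds Absolute-risk thresholds for categorical NRI and
#'   sensitivity/specificity (binary traits).
#' @param quantiles Population fractions for case capture (binary traits).
#'
#' @return An object of class `risk_projection` with [tidy()] and
#'   [glance()] methods.
#' @examples
#' sc <- risk_scenario("breast_cancer", rho = 0.4, r2_gx = 0.8)
#' pr <- project_accuracy(sc$design, sc$trait, sc$env,
#'                        risk_thresholds = 0.08, quantiles = c(0.1, 0.2, 0.5))
#' glance(pr)
#' tidy(pr)
#' @export
project_accuracy <- function(design, trait, env, scheme = "ols",
                             risk_thresholds = numeric(0),
                             quantiles = numeric(0)) {
  mom <- score_moments(design, trait, env)
  cs <- combine_scores(mom, env, scheme)
  metrics <- list()
  if (trait$kind == "binary") {
    metrics$auc <- tibble(
      metric = "auc", threshold = NA_real_,
      value = liability_auc(cs$r2_comb, trait$K)
    )
    if (length(risk_thresholds)) {
      nri <- categorical_nri(cs, trait, risk_thresholds)
      ss <- sens_spec(cs$r2_comb, trait$K, risk_thresholds)
      metrics$nri <- tibble(
        metric = rep(c("nri_case", "nri_control"), each = nrow(nri)),
        threshold = rep(nri$a, 2),
        value = c(nri$nri_case, nri$nri_control)
      )
      metrics$ss <- tibble(
        metric = rep(c("sensitivity", "specificity"), each = nrow(ss)),
        threshold = rep(ss$a, 2),
        value = c(ss$sensitivity, ss$specificity)
      )
    }
    cn <- continuous_nri(cs, trait)
    metrics$cnri <- tibble(
      metric = c("cnri_case", "cnri_control"), threshold = NA_real_,
      value = c(cn$cnri_case, cn$cnri_control)
    )
    metrics$idi <- tibble(
      metric = "idi", threshold = NA_real_, value = idi(cs, trait)
    )
    if (length(quantiles)) {
      metrics$capture <- tibble(
        metric = "capture", threshold = quantiles,
        value = case_capture(cs$r2_comb, trait$K, quantiles)
      )
    }
  }
  structure(
    list(
      design = design, trait = trait, env = env,
      moments = mom, combined = cs,
      metrics = dplyr::bind_rows(metrics)
    ),
    class = "risk_projection"
  )
}

#' @export
print.risk_projection <- function(x, ...) {
  cat("<risk_projection>\n")
  print(x$combined)
  if (nrow(x$metrics)) print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Tidy a risk projection into one row per metric
#'
#' @param x A [project_accuracy()] result.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `threshold`, `value`.
#' @export
tidy.risk_projection <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      metric = c("r2", "gamma"), threshold = NA_real_,
      value = c(x$combined$r2_comb, x$combined$gamma)
    ),
    x$metrics
  )
}

#' One-row summary of a risk projection
#'
#' @inheritParams tidy.risk_projection
#' @return A one-row tibble: scheme, training size, selection window,
#'   weights, combined R-squared, calibration, and AUC (binary traits).
#' @export
glance.risk_projection <- function(x, ...) {
  tibble(
    scheme = x$combined$scheme,
    n = x$design$n, p1 = x$design$p1,
    w1 = x$combined$w1, w2 = x$combined$w2,
    r2_comb = x$combined$r2_comb,
    gamma = x$combined$gamma,
    auc = if (x$trait$kind == "binary") {
      liability_auc(x$combined$r2_comb, x$trait$K)
    } else NA_real_
  )
}

#' Accuracy as a function of training sample size
#'
#' Evaluates an accuracy objective on a log-spaced grid of training sample
#' sizes for one or more combination schemes, optionally re-optimizing the
#' selection threshold at each size. The result is a tidy tibble suitable
#' for plotting with [autoplot()].
#'
#' @inheritParams project_accuracy
#' @param schemes Character vector of schemes to trace.
#' @param n_grid Training sizes; default 40 log-spaced points between
#'   `1e3` and `1e7`.
#' @param objective `"auc"` or `"r2"`.
#' @param optimize_p1 Re-optimize `p1` at each `n`? Otherwise use the
#'   design's `p1`.
#' @return A tibble of class `accuracy_curve` with columns `scheme`, `n`,
#'   `p1`, `value`.
#' @export
accuracy_curve <- function(design, trait, env,
                           schemes = c("polygenic", "environment", "ols"),
                           n_grid = 10^seq(3, 7, length.out = 40),
                           objective = c("auc", "r2"),
                           optimize_p1 = TRUE) {
  objective <- match.arg(objective)
  grid <- tidyr::expand_grid(scheme = schemes, n = n_grid)
  rows <- purrr::pmap(grid, function(scheme, n) {
    d <- design
    d$n <- n
    if (scheme == "environment") {
      v <- if (objective == "auc") {
        liability_auc(env$r2_xy, trait$K)
      } else env$r2_xy
      return(tibble(scheme = scheme, n = n, p1 = NA_real_, value = v))
    }
    if (optimize_p1) {
      opt <- optimize_threshold(d, trait, env, scheme, objective)
      tibble(scheme = scheme, n = n, p1 = opt$p1_opt, value = opt$value)
    } else {
      f <- objective_fn(d, trait, env, scheme, objective, a = 0.1)
      tibble(scheme = scheme, n = n, p1 = d$p1, value = f(log10(d$p1)))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_curve", class(out))
  attr(out, "objective") <- objective
  out
}

# -------------------------------------------------------------------------
# Scenario report tables

#' Reference tables for the preset scenarios
#'
#' Recomputes the worked-scenario summary grids from the analytic model.
#' Available table ids:
#'
#' * `"cvd_auc"`: AUC of environment, polygenic and combined (unweighted /
#'   weighted, `rho` 0.1 and 0.4) scores at genome-wide selection, at the
#'   per-scheme optimal threshold, and at infinite training size.
#' * `"cvd_nri10"`: case/control NRI at 10% risk for the same grid.
#' * `"cvd_nri20"`: weighted-score (`rho` 0.4) NRI at 20% risk,
#'   continuous NRI and IDI.
#' * `"bc_auc"`: breast-cancer AUC grid over `r2_gx` in (0.1, 0.8) and
#'   `rho` in (0.1, 0.4), weighted combination.
#' * `"bc_nri8"`: breast-cancer (`rho` 0.4, `r2_gx` 0.8) NRI at 8% risk,
#'   continuous NRI and IDI.
#' * `"bc_capture"`: percentage of cases in the top 10/20/50% of the
#'   population for polygenic, environmental and weighted combined scores.
#'
#' Sensitivity variants (changed prevalence or null proportion) are
#' obtained through the `K` and `pi0` overrides.
#'
#' @param id Table identifier, see Details.
#' @param K,pi0 Optional prevalence / null-proportion overrides passed to
#'   [risk_scenario()].
#' @return A tidy tibble; columns vary by table and always include the
#'   selection threshold `p1` and training size label `n_cases`.
#' @export
scenario_table <- function(id = c("cvd_auc", "cvd_nri10", "cvd_nri20",
                                  "bc_auc", "bc_nri8", "bc_capture"),
                           K = NULL, pi0 = NULL) {
  id <- match.arg(id)
  scen <- function(name, rho = NULL, r2_gx = NULL, n = NULL, p1 = 5e-8) {
    risk_scenario(name, rho = rho, r2_gx = r2_gx, K = K, pi0 = pi0,
                  n = n, p1 = p1)
  }
  base <- if (startsWith(id, "cvd")) "cvd" else "breast_cancer"
  s0 <- scen(base)
  n_pub <- s0$design$n
  cases <- round(n_pub * s0$trait$P)

  cell <- function(scheme, rho, n, p1, r2_gx = NULL, metric, a = NULL,
                   q = NULL) {
    sc <- scen(base, rho = rho, r2_gx = r2_gx, n = n, p1 = p1 %||% 1)
    if (is.null(p1)) { # optimize for the given objective family
      obj <- if (metric %in% c("auc", "capture")) "auc" else metric
      obj <- if (metric %in% c("cnri_case", "cnri_control", "idi")) metric else obj
      opt <- optimize_threshold(sc$design, sc$trait, sc$env, scheme, obj,
                                a = a %||% 0.1)
      sc$design$p1 <- opt$p1_opt
    }
    mom <- suppressWarnings(score_moments(sc$design, sc$trait, sc$env))
    cs <- suppressWarnings(combine_scores(mom, sc$env, scheme))
    val <- switch(metric,
      auc = liability_auc(cs$r2_comb, sc$trait$K),
      nri_case = categorical_nri(cs, sc$trait, a)$nri_case,
      nri_control = categorical_nri(cs, sc$trait, a)$nri_control,
      cnri_case = continuous_nri(cs, sc$trait)$cnri_case,
      cnri_control = continuous_nri(cs, sc$trait)$cnri_control,
      idi = idi(cs, sc$trait),
      capture = case_capture(cs$r2_comb, sc$trait$K, q)
    )
    tibble(
      scheme = scheme, rho = sc$env$rho, r2_gx = sc$env$r2_gx,
      n = n, p1 = sc$design$p1, metric = metric,
      threshold = a %||% q %||% NA_real_, value = val
    )
  }

  gw <- 5e-8
  out <- switch(id,
    cvd_auc = {
      specs <- tidyr::expand_grid(
        scheme = c("environment", "polygenic", "unweighted", "ols"),
        rho = c(0.1, 0.4),
        n = c(n_pub, Inf),
        p1_fixed = c(TRUE, FALSE)
      )
      specs <- dplyr::filter(
        specs,
        !(scheme %in% c("environment", "polygenic") & rho == 0.4),
        !(is.infinite(n) & !p1_fixed),
        !(scheme == "environment" & !p1_fixed) # no threshold to optimize
      )
      dplyr::bind_rows(purrr::pmap(specs, function(scheme, rho, n, p1_fixed) {
        cell(scheme, rho, n, if (p1_fixed) gw else NULL, metric = "auc")
      }))
    },
    cvd_nri10 = {
      specs <- tidyr::expand_grid(
        scheme = c("unweighted", "ols"), rho = c(0.1, 0.4),
        n = c(n_pub, Inf), m = c("nri_case", "nri_control")
      )
      dplyr::bind_rows(purrr::pmap(specs, function(scheme, rho, n, m) {
        cell(scheme, rho, n, gw, metric = m, a = 0.10)
      }))
    },
    cvd_nri20 = {
      specs <- tidyr::expand_grid(
        n = c(n_pub, Inf),
        m = c("nri_case", "nri_control", "cnri_case", "cnri_control", "idi")
      )
      dplyr::bind_rows(purrr::pmap(specs, function(n, m) {
        cell("ols", 0.4, n, gw, metric = m,
             a = if (startsWith(m, "nri")) 0.20 else NULL)
      }))
    },
    bc_auc = {
      specs <- tidyr::expand_grid(
        r2_gx = c(0.1, 0.8), rho = c(0.1, 0.4),
        n = c(n_pub, Inf), p1_fixed = c(TRUE, FALSE)
      )
      specs <- dplyr::filter(specs, !(is.infinite(n) & !p1_fixed))
      env_poly <- dplyr::bind_rows(
        cell("environment", 0.1, n_pub, gw, metric = "auc"),
        cell("polygenic", 0.1, n_pub, gw, metric = "auc"),
        cell("polygenic", 0.1, n_pub, NULL, metric = "auc"),
        cell("polygenic", 0.1, Inf, gw, metric = "auc")
      )
      dplyr::bind_rows(
        env_poly,
        purrr::pmap(specs, function(r2_gx, rho, n, p1_fixed) {
          cell("ols", rho, n, if (p1_fixed) gw else NULL, r2_gx = r2_gx,
               metric = "auc")
        })
      )
    },
    bc_nri8 = {
      specs <- tidyr::expand_grid(
        n = c(n_pub, Inf),
        m = c("nri_case", "nri_control", "cnri_case", "cnri_control", "idi")
      )
      dplyr::bind_rows(purrr::pmap(specs, function(n, m) {
        cell("ols", 0.4, n, gw, r2_gx = 0.8, metric = m,
             a = if (startsWith(m, "nri")) 0.08 else NULL)
      }))
    },
    bc_capture = {
      specs <- tidyr::expand_grid(
        scheme = c("polygenic", "environment", "ols"),
        n = c(n_pub, Inf), p1_fixed = c(TRUE, FALSE),
        q = c(0.1, 0.2, 0.5)
      )
      specs <- dplyr::filter(
        specs,
        !(is.infinite(n) & !p1_fixed),
        !(scheme == "environment" & !p1_fixed)
      )
      dplyr::bind_rows(purrr::pmap(specs, function(scheme, n, p1_fixed, q) {
        cell(scheme, 0.4, n, if (p1_fixed) gw else NULL, r2_gx = 0.8,
             metric = "capture", q = q)
      }))
    }
  )
  out$n_cases <- ifelse(is.infinite(out$n), Inf, round(out$n * s0$trait$P))
  out
}

#' Run scenarios described in a configuration file
#'
#' Reads a YAML configuration with a `scenarios` list; each entry names a
#' preset and may override `rho`, `r2_gx`, `K`, `pi0`, `p1`, `n`,
#' `scheme`, `risk_thresholds` and `quantiles`. Each scenario is
#' evaluated with [project_accuracy()] and the results stacked in a tidy
#' table (one row per scenario, scheme and metric). Derived intermediate
#' quantities (threshold, scale factor, shrinkage, moments, weights,
#' calibration) are reported alongside via [glance()] columns.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @param out Optional path; when given, the table is written as CSV.
#' @return A tibble with columns `scenario`, `scheme`, `rho`, `p1`, `n`,
#'   `metric`, `threshold`, `value`.
#' @export
run_scenario <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  entries <- config$scenarios
  if (is.null(entries)) {
    res <- tibble(
      scenario = character(), scheme = character(), rho = numeric(),
      p1 = numeric(), n = numeric(), metric = character(),
      threshold = numeric(), value = numeric()
    )
  } else {
    res <- dplyr::bind_rows(lapply(entries, function(e) {
      if (is.null(e[["name"]])) abort("config scenario entry is missing `name`.")
      sc <- risk_scenario(
        e[["name"]],
        rho = e[["rho"]], r2_gx = e[["r2_gx"]], K = e[["K"]],
        pi0 = e[["pi0"]], p1 = e[["p1"]] %||% 5e-8, n = e[["n"]]
      )
      pr <- project_accuracy(
        sc$design, sc$trait, sc$env,
        scheme = e[["scheme"]] %||% "ols",
        risk_thresholds = unlist(e[["risk_thresholds"]]) %||% numeric(0),
        quantiles = unlist(e[["quantiles"]]) %||% numeric(0)
      )
      td <- tidy(pr)
      tibble(
        scenario = e[["name"]], scheme = pr$combined$scheme,
        rho = sc$env$rho, p1 = sc$design$p1, n = sc$design$n,
        metric = td$metric, threshold = td$threshold, value = td$value
      )
    }))
  }
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}
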