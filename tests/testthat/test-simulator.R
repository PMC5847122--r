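# Reduced-scale Monte-Carlo agreement checks between the analytic moments/
# metrics and the individual-level simulator. All seeds fixed; agreement is
# asserted within 3 standard errors of the replicate mean.

se_mean <- function(x) sd(x) / sqrt(length(x))

small_config <- function(kind = "binary", rho = 0.3, n_reps = 150,
                         seed = 1234, p1 = 0.05) {
  d <- polygenic_design(n = 2000, m = 1000, p1 = p1, pi0 = 0.9,
                        h2_chip = 0.3)
  tr <- if (kind == "binary") trait_model("binary", K = 0.15, P = 0.3)
        else trait_model("continuous")
  env <- env_model(r2_xy = 0.1, r2_gx = 0.4, rho = rho)
  sim_config(d, tr, env, n_target = 2000, n_reps = n_reps, seed = seed)
}

test_that("effect draws have the mixture moments and shared-null structure", {
  set.seed(42)
  cfg <- small_config()
  n_nonnull <- s_b2 <- s_ab <- s_a2 <- numeric(200)
  for (i in 1:200) {
    eff <- draw_effects(cfg)
    n_nonnull[i] <- sum(eff$beta != 0)
    s_b2[i] <- sum(eff$beta^2)
    s_ab[i] <- sum(eff$alpha * eff$beta)
    s_a2[i] <- sum(eff$alpha^2)
    expect_true(all(eff$alpha[eff$beta == 0] == 0)) # shared null set
  }
  expect_within_3se(mean(n_nonnull), 100, se_mean(n_nonnull), "non-null count")
  expect_within_3se(mean(s_b2), 0.3, se_mean(s_b2), "genetic variance")
  e <- cfg$env
  expect_within_3se(mean(s_a2), e$r2_xy * e$r2_gx, se_mean(s_a2),
                    "genetic variance of X")
  expect_within_3se(mean(s_ab), e$rho * sqrt(0.3 * e$r2_xy * e$r2_gx),
                    se_mean(s_ab), "chip covariance")
})

test_that("perfect genetic correlation collapses the two effect vectors", {
  d <- polygenic_design(n = 1000, m = 500, p1 = 1, pi0 = 0.5, h2_chip = 0.2)
  # rho = 1 with r2_xy * r2_gx = h2_chip forces alpha = beta
  env <- env_model(r2_xy = 0.4, r2_gx = 0.5, rho = 1)
  cfg <- sim_config(d, trait_model("continuous"), env, 100, 1, seed = 5)
  set.seed(5)
  eff <- draw_effects(cfg)
  expect_equal(eff$alpha, eff$beta, tolerance = 1e-12)
})

test_that("training selection keeps everything when the window is open", {
  cfg <- small_config(p1 = 1)
  set.seed(9)
  eff <- draw_effects(cfg)
  w <- simulate_training(cfg, eff)
  expect_true(all(w != 0))
  # infinite information: estimates converge on the truth
  cfg_big <- cfg
  cfg_big$design$n <- 1e12
  set.seed(9)
  eff <- draw_effects(cfg_big)
  w <- simulate_training(cfg_big, eff)
  expect_lt(max(abs(w - eff$beta)), 1e-4)
})

test_that("simulated cohorts reproduce the prescribed population moments", {
  cfg <- small_config(rho = 0.3, n_reps = 60, seed = 2024)
  reps <- simulate_replicates(cfg, scheme = "ols", a = 0.1, q = 0.2)
  expect_within_3se(mean(reps$var_y), 1, se_mean(reps$var_y), "var(Y)")
  expect_within_3se(mean(reps$cov_xy), cfg$env$r2_xy, se_mean(reps$cov_xy),
                    "cov(X,Y)")
  expect_within_3se(mean(reps$prevalence), cfg$trait$K,
                    se_mean(reps$prevalence), "prevalence")
})

test_that("analytic score moments agree with the simulator at reduced scale", {
  for (kind in c("continuous", "binary")) {
    cfg <- small_config(kind, rho = 0.3, n_reps = 200, seed = 31)
    mom <- score_moments(cfg$design, cfg$trait, cfg$env)
    reps <- simulate_replicates(cfg, scheme = "ols")
    expect_within_3se(mean(reps$cov_sy), mom$cov_sy, se_mean(reps$cov_sy),
                      paste(kind, "cov(S,Y)"))
    expect_within_3se(mean(reps$var_s), mom$var_s, se_mean(reps$var_s),
                      paste(kind, "var(S)"))
    expect_within_3se(mean(reps$cov_sx), mom$cov_sx, se_mean(reps$cov_sx),
                      paste(kind, "cov(S,X)"))
  }
})

test_that("analytic discrimination and reclassification agree with the simulator", {
  cfg <- small_config("binary", rho = 0.3, n_reps = 150, seed = 99)
  mom <- score_moments(cfg$design, cfg$trait, cfg$env)
  cs <- combine_scores(mom, cfg$env, "ols")
  tr <- cfg$trait
  reps <- simulate_replicates(cfg, scheme = "ols", a = 0.1, q = 0.2)
  expect_within_3se(mean(reps$auc), liability_auc(cs$r2_comb, tr$K),
                    se_mean(reps$auc), "AUC")
  nri <- categorical_nri(cs, tr, 0.1)
  expect_within_3se(mean(reps$nri_case), nri$nri_case,
                    se_mean(reps$nri_case), "case NRI")
  expect_within_3se(mean(reps$nri_control), nri$nri_control,
                    se_mean(reps$nri_control), "control NRI")
  cn <- continuous_nri(cs, tr)
  expect_within_3se(mean(reps$cnri_case), cn$cnri_case,
                    se_mean(reps$cnri_case), "continuous case NRI")
  expect_within_3se(mean(reps$cnri_control), cn$cnri_control,
                    se_mean(reps$cnri_control), "continuous control NRI")
  expect_within_3se(mean(reps$idi), idi(cs, tr), se_mean(reps$idi), "IDI")
  expect_within_3se(mean(reps$capture), case_capture(cs$r2_comb, tr$K, 0.2),
                    se_mean(reps$capture), "capture")
})

test_that("empirical metrics recover trivial extremes", {
  tr <- trait_model("binary", K = 0.2)
  set.seed(12)
  y <- rnorm(4000)
  d <- as.integer(y > tr$tau)
  perfect <- empirical_metrics(tibble::tibble(score = y, d = d), tr)
  expect_gt(perfect$value[perfect$metric == "auc"], 0.99)
  random <- empirical_metrics(
    tibble::tibble(score = rnorm(4000), d = d), tr, q = 0.5
  )
  expect_equal(random$value[random$metric == "auc"], 0.5, tolerance = 0.05)
  expect_equal(random$value[random$metric == "capture"], 50, tolerance = 5)
  expect_error(
    empirical_metrics(tibble::tibble(score = y, d = rep(0L, 4000)), tr),
    "cases"
  )
})

test_that("the simulator is bit-for-bit reproducible from its seed", {
  cfg <- small_config(n_reps = 3, seed = 777)
  expect_identical(simulate_replicates(cfg), simulate_replicates(cfg))
})
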