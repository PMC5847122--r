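cvd_combined <- function(rho = 0.1, scheme = "unweighted", ...) {
  sc <- risk_scenario("cvd", rho = rho, ...)
  list(
    sc = sc,
    cs = combine_scores(score_moments(sc$design, sc$trait, sc$env),
                        sc$env, scheme)
  )
}

test_that("risk mapping round-trips and anchors at the prevalence", {
  expect_equal(risk_from_score(0, 0, 0.15), 0.15)
  for (r2 in c(0.05, 0.3)) {
    for (a in c(0.02, 0.1, 0.4)) {
      x <- score_at_risk(a, r2, 0.15)
      expect_equal(risk_from_score(x, r2, 0.15), a, tolerance = 1e-10)
    }
    xs <- seq(-2, 2, by = 0.25)
    expect_true(all(diff(risk_from_score(xs, r2, 0.15)) > 0))
  }
  # threshold for 10% risk under the CVD environmental score, cross-checked
  # by root-finding the forward map
  aX <- score_at_risk(0.10, 0.052, 0.15)
  expect_equal(aX, qnorm(0.85) - sqrt(0.948) * qnorm(0.9), tolerance = 1e-12)
  root <- uniroot(function(x) risk_from_score(x, 0.052, 0.15) - 0.10,
                  c(-3, 3), tol = 1e-12)$root
  expect_equal(aX, root, tolerance = 1e-8)
})

test_that("the trivariate joint of liability and scores is coherent", {
  x <- cvd_combined(rho = 0.4, scheme = "ols")
  S <- trivariate_joint(x$cs)
  expect_equal(S, t(S))
  expect_true(min(eigen(S, symmetric = TRUE)$values) > -1e-10)
  expect_equal(S["y", "s"], x$cs$r2_comb)
  expect_equal(S["s", "s"], x$cs$r2_comb)
  # inconsistent parameters are refused
  bad <- x$cs
  bad$cov_gcomb_x <- 0.9
  expect_error(trivariate_joint(bad), "positive semi-definite")
})

test_that("MVN rectangle probabilities match Monte Carlo", {
  set.seed(505)
  for (i in 1:3) {
    A <- matrix(rnorm(9, sd = 0.5), 3)
    S <- crossprod(A) + diag(0.2, 3)
    lo <- c(-Inf, rnorm(1, -0.5), rnorm(1, -0.5))
    hi <- lo + c(Inf, abs(rnorm(1)) + 0.3, abs(rnorm(1)) + 0.3)
    hi[1] <- rnorm(1, 0.5)
    p <- prsproject:::mvn_rectangle(lo, hi, S)
    mc <- mc_mvn_rectangle(lo, hi, S, n = 1e6, seed = 600 + i)
    expect_within_3se(mc$p, p, mc$se, "rectangle probability")
  }
})

test_that("replacing a score by itself reclassifies nobody", {
  sc <- risk_scenario("cvd")
  cs <- combine_scores(score_moments(sc$design, sc$trait, sc$env),
                       sc$env, "environment")
  nri <- categorical_nri(cs, sc$trait, a = c(0.05, 0.10, 0.20))
  expect_equal(nri$nri_case, rep(0, 3))
  expect_equal(nri$nri_control, rep(0, 3))
  cn <- continuous_nri(cs, sc$trait)
  expect_equal(c(cn$cnri_case, cn$cnri_control), c(0, 0))
  expect_equal(idi(cs, sc$trait), 0)
})

test_that("categorical NRI matches trivariate Monte Carlo counting", {
  x <- cvd_combined(rho = 0.4, scheme = "ols")
  tr <- x$sc$trait
  a <- 0.10
  nri <- categorical_nri(x$cs, tr, a)
  S <- trivariate_joint(x$cs)
  set.seed(77)
  n <- 1e6
  Z <- matrix(rnorm(n * 3), n) %*% chol(S)
  aX <- score_at_risk(a, x$cs$r2_xy, tr$K)
  aS <- score_at_risk(a, x$cs$r2_comb, tr$K)
  case <- Z[, 1] > tr$tau
  up <- Z[, 3] > aS & Z[, 2] <= aX
  down <- Z[, 3] <= aS & Z[, 2] > aX
  est <- mean(up[case]) - mean(down[case])
  se <- sd(up[case] - down[case]) / sqrt(sum(case))
  expect_within_3se(est, nri$nri_case, se, "case NRI")
  est0 <- mean(down[!case]) - mean(up[!case])
  se0 <- sd(down[!case] - up[!case]) / sqrt(sum(!case))
  expect_within_3se(est0, nri$nri_control, se0, "control NRI")
})

test_that("NRI components remain in [-1, 1] across parameter draws", {
  set.seed(606)
  for (i in 1:10) {
    d <- polygenic_design(
      n = sample(c(5000, 5e4, 5e5), 1), m = 1e4,
      p1 = 10^runif(1, -6, 0), pi0 = runif(1, 0.5, 0.99),
      h2_chip = runif(1, 0.1, 0.7)
    )
    tr <- trait_model("binary", K = runif(1, 0.02, 0.3))
    env <- env_model(runif(1, 0.01, 0.2), runif(1, 0, 1), runif(1, 0, 0.8))
    cs <- suppressWarnings(
      combine_scores(score_moments(d, tr, env), env,
                     sample(c("ols", "unweighted"), 1))
    )
    nri <- categorical_nri(cs, tr, a = runif(1, 0.02, 0.4))
    cn <- continuous_nri(cs, tr)
    vals <- c(nri$nri_case, nri$nri_control, cn$cnri_case, cn$cnri_control)
    expect_true(all(vals >= -1 & vals <= 1))
  }
})

test_that("a score difference uncorrelated with liability has zero case cNRI", {
  x <- cvd_combined()
  cs <- x$cs
  # surgically equalize the variances so cov(Y, comb - X) = 0
  cs$r2_comb <- cs$r2_xy
  cs$cov_gcomb_x <- cs$r2_xy * 0.5 # keep var(comb - X) > 0
  cn <- continuous_nri(cs, x$sc$trait)
  expect_equal(cn$cnri_case, 0, tolerance = 1e-10)
  expect_equal(cn$cnri_control, 0, tolerance = 1e-10)
})

test_that("IDI quadrature agrees with its closed form and is nonnegative for OLS", {
  for (name in c("cvd", "breast_cancer")) {
    for (rho in c(0.1, 0.4)) {
      for (p1 in c(5e-8, 0.01, 0.5)) {
        sc <- risk_scenario(name, rho = rho, p1 = p1)
        cs <- combine_scores(score_moments(sc$design, sc$trait, sc$env),
                             sc$env, "ols")
        v <- idi(cs, sc$trait)
        cf <- risk_gap_closed_form(cs$r2_comb, sc$trait$K) -
          risk_gap_closed_form(cs$r2_xy, sc$trait$K)
        expect_equal(v, cf, tolerance = 1e-8)
        expect_gte(v, 0)
      }
    }
  }
})
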