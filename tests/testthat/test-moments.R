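test_that("truncation factor equals the normal second-moment integral", {
  expect_equal(truncation_factor(Inf, 0), 0.5)
  expect_equal(truncation_factor(2, 2), 0)
  expect_equal(truncation_factor(Inf, -Inf), 1)
  expect_equal(truncation_factor(Inf, 1.959964),
               quad_tail_moment(40, 1.959964), tolerance = 1e-10)
  # 50 random windows against adaptive quadrature
  set.seed(101)
  for (i in 1:50) {
    x <- sort(rnorm(2, sd = 2))
    expect_equal(truncation_factor(x[2], x[1]),
                 quad_tail_moment(x[2], x[1]), tolerance = 1e-9)
  }
  expect_error(truncation_factor(0, 1), "x0 >= x1")
})

test_that("selection quantiles shrink with training information", {
  d <- polygenic_design(n = 2000, m = 1000, p1 = 0.05, pi0 = 0.9,
                        h2_chip = 0.3)
  tr <- trait_model("continuous")
  sq <- selection_quantiles(d, tr)
  expect_identical(sq$q0, Inf)
  expect_identical(sq$r0, Inf)
  expect_true(sq$theta > 0 && sq$theta <= 1)
  expect_equal(sq$r1, sq$q1 * sq$theta)

  # infinite training: exact theta = 0 limit
  di <- polygenic_design(n = Inf, m = 1000, p1 = 0.05, pi0 = 0.9,
                         h2_chip = 0.3)
  expect_identical(selection_quantiles(di, tr)$theta, 0)
  expect_equal(selection_quantiles(di, tr)$r1, 0)

  # genome-wide significance quantile (frozen from direct evaluation)
  cvd <- risk_scenario("cvd")
  expect_equal(selection_quantiles(cvd$design, cvd$trait)$q1,
               5.4513, tolerance = 1e-4)
})

test_that("complete noiseless score attains the chip heritability", {
  d <- polygenic_design(n = Inf, m = 1000, p0 = 0, p1 = 1, pi0 = 0.5,
                        h2_chip = 0.3)
  mom <- score_moments(d, trait_model("continuous"), env_model(0.1, 0.5, 0))
  expect_equal(mom$cov_sy, 0.3)
  expect_equal(mom$var_s, 0.3)
  expect_equal(mom$cov_sy^2 / mom$var_s, 0.3)
  # same limit holds through the binary pipeline on the liability scale
  db <- polygenic_design(n = Inf, m = 1000, p1 = 1, pi0 = 0.5, h2_chip = 0.3)
  momb <- score_moments(db, trait_model("binary", K = 0.1, P = 0.4),
                        env_model(0.1, 0.5, 0))
  expect_equal(momb$cov_sy^2 / momb$var_s, 0.3)
})

test_that("zero genetic correlation removes the score-environment covariance", {
  sc <- risk_scenario("cvd", rho = 0)
  mom <- score_moments(sc$design, sc$trait, sc$env)
  expect_identical(mom$cov_sx, 0)
  sc4 <- risk_scenario("cvd", rho = 0.4)
  expect_gt(score_moments(sc4$design, sc4$trait, sc4$env)$cov_sx, 0)
})

test_that("score R2 is nondecreasing in n and bounded by chip heritability", {
  for (name in c("cvd", "breast_cancer", "height")) {
    sc <- risk_scenario(name, p1 = 0.05)
    r2 <- vapply(10^seq(3, 7, length.out = 12), function(n) {
      sc$design$n <- n
      mom <- score_moments(sc$design, sc$trait, sc$env)
      mom$cov_sy^2 / mom$var_s
    }, numeric(1))
    expect_true(all(diff(r2) > -1e-12), label = paste(name, "monotone in n"))
    expect_true(all(r2 <= sc$design$h2_chip + 1e-10))
  }
  # property over random parameter draws
  set.seed(202)
  for (i in 1:40) {
    d <- polygenic_design(
      n = sample(c(500, 5000, 5e4, Inf), 1),
      m = sample(c(100, 1000, 1e5), 1),
      p1 = 10^runif(1, -8, 0),
      pi0 = runif(1, 0, 0.999),
      h2_chip = runif(1, 0.01, 1)
    )
    tr <- if (runif(1) < 0.5) trait_model("continuous") else
      trait_model("binary", K = runif(1, 0.01, 0.5), P = runif(1, 0.1, 0.9))
    mom <- suppressWarnings(
      score_moments(d, tr, env_model(0.05, 0.3, runif(1, -1, 1)))
    )
    if (!mom$degenerate) {
      expect_lte(mom$cov_sy^2 / mom$var_s, d$h2_chip + 1e-10)
    }
  }
})

test_that("binary and continuous pipelines agree under the scale identity", {
  # forcing the observed-to-liability factor to 1 and mapping the binary
  # effective sample size n/(P(1-P)) onto the continuous n must reproduce
  # the continuous moments exactly
  db <- polygenic_design(n = 10000, m = 2000, p1 = 0.01, pi0 = 0.9,
                         h2_chip = 0.4)
  trb <- trait_model("binary", K = 0.2, P = 0.35)
  trb$c <- 1
  env <- env_model(0.06, 0.4, 0.3)
  momb <- score_moments(db, trb, env)
  dc <- db
  dc$n <- db$n / (trb$P * (1 - trb$P))
  momc <- score_moments(dc, trait_model("continuous"), env)
  expect_equal(momb$cov_sy, momc$cov_sy, tolerance = 1e-12)
  expect_equal(momb$var_s, momc$var_s, tolerance = 1e-12)
  expect_equal(momb$cov_sx, momc$cov_sx, tolerance = 1e-12)
})

test_that("an empty selection window flags a degenerate score", {
  d <- polygenic_design(n = 1000, m = 100, p0 = 1e-300, p1 = 2e-300,
                        pi0 = 0.9, h2_chip = 0.3)
  expect_warning(
    mom <- score_moments(d, trait_model("continuous"), env_model(0, 0, 0)),
    "degenerate"
  )
  expect_true(mom$degenerate)
})
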