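test_that("binomial detection-difference SE matches simulation", {
  se <- se_delta_effect(0.2, 130)
  expect_equal(se, sqrt(2 * 0.2 * 0.8 * 130))
  # oracle: SD of simulated two-arm binomial count differences
  set.seed(3)
  draws <- rbinom(1e5, 130, 0.2) - rbinom(1e5, 130, 0.2)
  expect_equal(sd(draws), se, tolerance = 0.02)

  # p(1-p) maximal at one half; degenerate prevalence rejected
  expect_gt(se_delta_effect(0.5, 130), se_delta_effect(0.2, 130))
  expect_gt(se_delta_effect(0.5, 130), se_delta_effect(0.9, 130))
  expect_error(se_delta_effect(0, 130), "strictly between")
})

test_that("cost SEs scale with the CV and combine in quadrature", {
  expect_equal(se_cost(67357, 0.175), 11787.475)
  expect_equal(se_cost(1234, 0), 0)
  expect_equal(se_delta_cost(10, 10), 10 * sqrt(2))
  expect_equal(se_delta_cost(3, 4), 5)
  expect_error(se_delta_cost(1, 1, cov_ab = 5), "infeasible")
})

test_that("Fieller interval degenerates, bounds and unbounds correctly", {
  # all SEs zero: interval collapses to the point ratio
  fi0 <- fieller_ci(100, 5, 0, 0)
  expect_equal(c(fi0$lower, fi0$point, fi0$upper), rep(20, 3))

  # bounded case contains the point
  fi <- fieller_ci(10, 5, 1, 0.1)
  expect_equal(fi$status, "bounded")
  expect_lt(fi$lower, fi$point)
  expect_gt(fi$upper, fi$point)

  # as the error rate grows (z -> 0) the bounds converge to the point
  fi_narrow <- fieller_ci(10, 5, 1, 0.1, alpha = 0.999)
  expect_equal(fi_narrow$lower, fi$point, tolerance = 1e-3)
  expect_equal(fi_narrow$upper, fi$point, tolerance = 1e-3)

  # effect difference indistinguishable from zero: unbounded set
  fi_inf <- fieller_ci(77065, 1, 12000, se_delta_effect(0.2, 130))
  expect_equal(fi_inf$status, "unbounded")
  expect_true(is.infinite(fi_inf$upper))
  expect_true(is.finite(fi_inf$lower))
})

test_that("Fieller bounds agree with a Monte-Carlo ratio oracle", {
  # bivariate-normal draws of (dC, dE); the 2.5/97.5 percentiles of the
  # ratio estimate the Fieller bounds when dE stays away from zero
  set.seed(21)
  for (k in 1:5) {
    de <- runif(1, 3, 9); dc <- runif(1, 1e4, 8e4)
    se_e <- de * runif(1, 0.05, 0.12); se_c <- dc * runif(1, 0.08, 0.2)
    rho <- runif(1, -0.4, 0.4); cv <- rho * se_c * se_e
    fi <- fieller_ci(dc, de, se_c, se_e, cv)
    expect_equal(fi$status, "bounded")
    M <- 2e5
    zc <- rnorm(M); ze <- rnorm(M)
    ratio <- (dc + se_c * zc) /
      (de + se_e * (rho * zc + sqrt(1 - rho^2) * ze))
    q <- quantile(ratio, c(0.025, 0.975), names = FALSE)
    expect_equal(fi$lower, q[1], tolerance = 0.02)
    expect_equal(fi$upper, q[2], tolerance = 0.02)
  }
})

test_that("delta-method INB interval behaves and respects conventions", {
  # no uncertainty: interval equals the point
  ci0 <- inb_ci(14634, 5, 10000, 130, se_c = 0, se_e = 0,
                spec = uncertainty_spec(cov_ce = 0))
  expect_equal(ci0$lower, ci0$point)
  expect_equal(ci0$upper, ci0$point)

  # width nondecreasing in the cost SE
  w1 <- with(inb_ci(14634, 5, 10000, 130, 5000, 2), upper - lower)
  w2 <- with(inb_ci(14634, 5, 10000, 130, 9000, 2), upper - lower)
  expect_gte(w2, w1)

  # the two covariance sign conventions move the width in opposite ways
  sp_alg <- uncertainty_spec(cov_ce = 4000, cov_convention = "algebraic")
  sp_pub <- uncertainty_spec(cov_ce = 4000, cov_convention = "as_published")
  wa <- with(inb_ci(14634, 5, 10000, 130, 9000, 2, sp_alg), upper - lower)
  wp <- with(inb_ci(14634, 5, 10000, 130, 9000, 2, sp_pub), upper - lower)
  w0 <- with(inb_ci(14634, 5, 10000, 130, 9000, 2), upper - lower)
  expect_lt(wa, w0)
  expect_gt(wp, w0)

  # infeasible covariance is refused, naming the offender
  expect_error(
    inb_ci(100, 1, 10000, 130, 10, 0.001,
           uncertainty_spec(cov_ce = 1e9)),
    "cov_ce")
})

test_that("paired bootstrap is seed-deterministic and self-consistent", {
  co <- fixture_cohort()
  b1 <- bootstrap_pairwise(co, "mpmri_or_pet", "mpmri", B = 300, seed = 5)
  b2 <- bootstrap_pairwise(co, "mpmri_or_pet", "mpmri", B = 300, seed = 5)
  expect_identical(b1$inb_ci, b2$inb_ci)
  expect_identical(b1$ceac, b2$ceac)
  b3 <- bootstrap_pairwise(co, "mpmri_or_pet", "mpmri", B = 300, seed = 6)
  expect_false(identical(b1$inb_ci, b3$inb_ci))

  # identity resample (each patient exactly once) reproduces the points
  idx <- matrix(seq_len(130), ncol = 1)
  b_id <- bootstrap_pairwise(co, "mpmri_or_pet", "mpmri", indices = idx)
  expect_equal(b_id$draws$delta_e, b_id$point$delta_e)
  expect_equal(b_id$draws$delta_c, b_id$point$delta_c)
  expect_equal(unname(b_id$draws$inb[1, ]), unname(b_id$point$inb))
})

test_that("bootstrap of a strategy against itself is exactly null", {
  co <- fixture_cohort()
  b <- bootstrap_pairwise(co, "mpmri", "mpmri", B = 200, seed = 9)
  expect_true(all(b$draws$delta_e == 0))
  expect_true(all(b$draws$inb == 0))
  expect_equal(unname(b$ceac), rep(0, 3))  # no draw strictly positive
  expect_equal(b$prop_zero_delta_e, 1)
})
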