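test_that("reference cohort reproduces every strategy margin", {
  co <- fixture_cohort()
  expect_equal(nrow(co), 130L)
  expect_equal(sum(is_cspca(co)), 26L)
  for (s in builtin_strategies()) {
    ct <- contingency(co, s)
    expect_identical(c(ct$tp + ct$fp, ct$tp), table2_margins[[s$name]],
                     info = s$name)
  }
  # joint imaging cells fixed by inclusion-exclusion
  mri <- co$pirads >= 3; pet <- co$primary_score >= 3; dis <- is_cspca(co)
  expect_equal(sum(mri & pet), 17L)
  expect_equal(sum(mri & pet & dis), 13L)
  expect_equal(sum(!mri & pet), 8L)  # stepwise PET scans under the OR rule
})

test_that("reference cohort is deterministic and RNG-free", {
  set.seed(123)
  old_seed <- .Random.seed
  expect_identical(fixture_cohort(), fixture_cohort())
  expect_identical(.Random.seed, old_seed)
  # no PSA density within 0.01 of the referral threshold
  expect_true(all(abs(fixture_cohort()$psad - 0.15) >= 0.01))
})

test_that("simulated cohorts are reproducible and validate inputs", {
  expect_identical(simulate_cohort(500, seed = 4),
                   simulate_cohort(500, seed = 4))
  expect_false(identical(simulate_cohort(500, seed = 4),
                         simulate_cohort(500, seed = 5)))

  none <- simulate_cohort(200, performance_spec(prevalence = 0), seed = 2)
  expect_equal(sum(is_cspca(none)), 0L)

  # infeasible joint imaging positivity is refused with the valid range
  expect_error(
    performance_spec(joint_mri_pet = c(cspca = 0.9, benign = 4 / 104)),
    "feasible range")
})

test_that("large simulated cohorts match the target test accuracies", {
  ps <- performance_spec()
  co <- simulate_cohort(1e5, ps, seed = 17)
  dis <- is_cspca(co)
  mri <- co$pirads >= 3; pet <- co$primary_score >= 3
  psad <- co$psad > 0.15
  # empirical rates within 0.01 (absolute) of the generative targets
  expect_lt(abs(mean(dis) - ps$prevalence), 0.01)
  expect_lt(abs(mean(mri[dis]) - ps$sens[["mpmri"]]), 0.01)
  expect_lt(abs(mean(pet[dis]) - ps$sens[["pet"]]), 0.01)
  expect_lt(abs(mean(psad[dis]) - ps$sens[["psad"]]), 0.01)
  expect_lt(abs(mean(!mri[!dis]) - ps$spec[["mpmri"]]), 0.01)
  expect_lt(abs(mean(mri[dis] & pet[dis]) - ps$joint_mri_pet[["cspca"]]),
            0.01)
})

test_that("cohorts of 130 fluctuate around the reference margins", {
  bx <- t(vapply(1:200, function(seed) {
    co <- simulate_cohort(130, seed = seed)
    vapply(builtin_strategies(), function(s) sum(refers(s, co)), 0L)
  }, integer(6)))
  target <- vapply(table2_margins, `[`, 0L, 1)
  # means within binomial sampling error of the reference counts
  se <- sqrt(target * (130 - target) / 130 / 200) + 0.5
  expect_true(all(abs(colMeans(bx) - target) < 3 * se))
})

test_that("closed-form expectations agree with simulation", {
  ps <- performance_spec()
  ex <- strategy_expectations(ps, paradigm = "stepwise")
  co <- simulate_cohort(1e5, ps, seed = 23)
  strategies <- builtin_strategies()
  for (i in seq_len(nrow(ex))) {
    s <- strategies[[ex$strategy[i]]]
    expect_equal(mean(refers(s, co)), ex$e_referred[i], tolerance = 0.02,
                 info = s$name)
    expect_equal(mean(patient_costs(co, s, "stepwise")), ex$e_cost[i],
                 tolerance = 0.02, info = s$name)
  }
})
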