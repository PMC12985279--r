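strategies <- builtin_strategies()
costs <- unit_costs()

test_that("stepwise utilisation follows the clinical pathways", {
  co <- fixture_cohort()
  u_or <- utilization(co, strategies$mpmri_or_pet, "stepwise", costs)
  expect_equal(u_or$n_mpmri, 130L)
  expect_equal(u_or$n_pet, 8L)   # mpMRI-negative, PET-positive patients
  expect_equal(u_or$n_biopsy, 42L)
  expect_equal(u_or$n_pathology, u_or$n_biopsy)

  u_and <- utilization(co, strategies$psad_and_mpmri, "stepwise", costs)
  expect_equal(u_and$n_mpmri, 61L)  # only PSAD-elevated patients scanned
  expect_equal(u_and$n_pet, 0L)
  expect_equal(u_and$n_biopsy, 20L)

  u_all <- utilization(co, strategies$biopsy_all, "stepwise", costs)
  expect_equal(u_all$n_mpmri, 0L)
  expect_equal(u_all$n_psa, 130)

  u_pet_u <- utilization(co, strategies$pet, "universal", costs)
  expect_equal(u_pet_u$n_pet, 130L)
})

test_that("totals are exact sums of count times unit cost", {
  u <- list(n_psa = 130, n_mpmri = 0, n_pet = 0,
            n_biopsy = 130, n_pathology = 130)
  expect_equal(total_cost(u, costs), 116057.5)
  expect_equal(round_half_up(total_cost(u, costs)), 116058)

  u0 <- list(n_psa = 0, n_mpmri = 0, n_pet = 0, n_biopsy = 0,
             n_pathology = 0)
  expect_equal(total_cost(u0, costs), 0)

  u_or <- list(n_psa = 130, n_mpmri = 130, n_pet = 8,
               n_biopsy = 42, n_pathology = 42)
  expect_equal(total_cost(u_or, costs), 81990.9)

  # linear in unit costs: doubling every tariff doubles the total exactly
  doubled <- unit_costs(psa = 3.1, mpmri = 567, pet = 1876,
                        biopsy = 1618.8, pathology = 163.6)
  expect_identical(total_cost(u_or, doubled), 2 * total_cost(u_or, costs))
})

test_that("cost per detection divides total by detected", {
  expect_equal(round_half_up(cost_per_detection(116057.5, 26)), 4464)
  expect_equal(round_half_up(cost_per_detection(144421.5, 18)), 8023)
  expect_true(is.na(cost_per_detection(1000, 0)))
})

test_that("per-patient cost ledger reconciles with utilisation totals", {
  for (seed in 1:6) {
    co <- simulate_cohort(25, seed = seed)
    for (s in strategies) {
      for (par in c("stepwise", "universal")) {
        ledger <- patient_costs(co, s, par, costs)
        util <- utilization(co, s, par, costs)
        expect_equal(sum(ledger), total_cost(util, costs),
                     info = paste(s$name, par, "seed", seed))
      }
    }
  }
})

test_that("universal allocation never costs less than stepwise", {
  for (seed in 1:6) {
    co <- simulate_cohort(80, seed = seed)
    for (s in strategies) {
      uni <- total_cost(utilization(co, s, "universal", costs), costs)
      step <- total_cost(utilization(co, s, "stepwise", costs), costs)
      expect_gte(uni, step)
    }
  }
})

test_that("the PSA multiplier scales only the assay line", {
  co <- fixture_cohort()
  c3 <- unit_costs(psa_multiplier = 3)
  u1 <- utilization(co, strategies$biopsy_all, "stepwise", costs)
  u3 <- utilization(co, strategies$biopsy_all, "stepwise", c3)
  expect_equal(u3$n_psa, 3 * u1$n_psa)
  expect_equal(total_cost(u3, c3) - total_cost(u1, costs),
               2 * 130 * 1.55)
})

test_that("strategy summaries tie counts, misses and costs together", {
  co <- fixture_cohort()
  s <- summarize_strategy(co, strategies$psad, costs, "stepwise")
  expect_equal(s$biopsies, 61L)
  expect_equal(s$cspca_detected, 17L)
  expect_equal(s$cspca_missed, 9L)
  expect_equal(s$biopsies_avoided, 130L - 61L)

  tab <- summarize_strategies(co, strategies, costs, "stepwise")
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$cspca_missed, 26L - tab$cspca_detected)
  expect_equal(tab$biopsies_avoided, 130L - tab$biopsies)
})
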