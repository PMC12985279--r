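strategies <- builtin_strategies()

test_that("the six referral rules match their clinical definitions", {
  # one patient per interesting boundary
  co <- mk_cohort(psad = c(0.15, 0.16, 0.20, 0.10),
                  pirads = c(2L, 2L, 2L, 3L),
                  primary = c(2L, 4L, 2L, 2L),
                  isup = c(0L, 2L, 2L, 0L))
  expect_equal(refers(strategies$biopsy_all, co), rep(TRUE, 4))
  # strict inequality: a tie at exactly 0.15 is not referred
  expect_equal(refers(strategies$psad, co), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(refers(strategies$mpmri, co), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(refers(strategies$pet, co), c(FALSE, TRUE, FALSE, FALSE))
  # disjunction referred by PET alone; conjunction fails without mpMRI
  expect_equal(refers(strategies$mpmri_or_pet, co),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(refers(strategies$psad_and_mpmri, co),
               c(FALSE, FALSE, FALSE, FALSE))
})

test_that("missing imaging scores classify as not referred, with warning", {
  co <- tiny_cohort()
  co$pirads[1] <- NA
  expect_warning(out <- refers(strategies$mpmri, co), "not referred")
  expect_false(out[1])
  # OR rule: a positive PET still refers despite the missing mpMRI score
  expect_silent(out2 <- refers(strategies$mpmri_or_pet, co))
  expect_true(out2[1])
})

test_that("contingency matches per-record predicate counting", {
  # independent brute-force oracle: loop over records with literal rules
  brute <- function(co, rule) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(nrow(co))) {
      r <- co[i, ]
      pos <- isTRUE(rule(r))
      dis <- r$isup >= 2
      if (pos && dis) tp <- tp + 1L else if (pos) fp <- fp + 1L
      else if (dis) fn <- fn + 1L else tn <- tn + 1L
    }
    list(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  rules <- list(
    biopsy_all = function(r) TRUE,
    psad = function(r) r$psad > 0.15,
    mpmri = function(r) r$pirads >= 3,
    pet = function(r) r$primary_score >= 3,
    mpmri_or_pet = function(r) isTRUE(r$pirads >= 3) ||
      isTRUE(r$primary_score >= 3),
    psad_and_mpmri = function(r) r$psad > 0.15 && isTRUE(r$pirads >= 3)
  )
  for (seed in 1:8) {
    co <- simulate_cohort(10, seed = seed)
    for (nm in names(rules)) {
      ct <- contingency(co, strategies[[nm]])
      expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
                   brute(co, rules[[nm]]),
                   info = paste(nm, "seed", seed))
      expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, nrow(co))
    }
  }
  expect_error(contingency(fixture_cohort()[0, ], strategies$mpmri),
               "empty")
})

test_that("diagnostic metrics follow the 2x2 definitions", {
  m <- diagnostic_metrics(list(tp = 17, fp = 17, fn = 9, tn = 87))
  expect_equal(m[["sensitivity"]], 17 / 26)
  expect_equal(m[["specificity"]], 87 / 104)
  expect_equal(m[["ppv"]], 0.5)
  expect_equal(m[["accuracy"]], 104 / 130)

  # refer-everyone: perfect sensitivity, NPV undefined
  all_in <- diagnostic_metrics(list(tp = 26, fp = 104, fn = 0, tn = 0))
  expect_equal(all_in[["sensitivity"]], 1)
  expect_true(is.na(all_in[["npv"]]))

  perfect <- diagnostic_metrics(list(tp = 26, fp = 0, fn = 0, tn = 104))
  expect_true(all(perfect == 1))

  expect_error(diagnostic_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "all zero")
})

test_that("number needed to biopsy is biopsies per detection", {
  expect_equal(nnt(130, 26), 5.0)
  expect_equal(round(nnt(25, 18), 1), 1.4)
  expect_equal(round(nnt(42, 22), 1), 1.9)
  expect_true(is.na(nnt(10, 0)))
  expect_error(nnt(5, 10))
})

test_that("composite strategies obey set-logic bounds on any cohort", {
  for (seed in 1:10) {
    co <- simulate_cohort(150, seed = seed)
    det <- vapply(strategies, function(s) contingency(co, s)$tp, 0L)
    bx <- vapply(strategies, function(s) sum(refers(s, co)), 0L)
    expect_gte(det[["mpmri_or_pet"]], max(det[["mpmri"]], det[["pet"]]))
    expect_lte(bx[["psad_and_mpmri"]], min(bx[["psad"]], bx[["mpmri"]]))
    # tp + fn is strategy-independent
    totals <- vapply(strategies, function(s) {
      ct <- contingency(co, s); ct$tp + ct$fn
    }, 0L)
    expect_true(all(totals == sum(is_cspca(co))))
  }
})
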