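#' Deterministic 130-patient reference cohort
#'
#' Builds, without any random number generation, a cohort of 130 patients
#' (26 with csPCa) whose per-strategy referral and detection margins are:
#' biopsy-all (130, 26), PSAD > 0.15 (61, 17), mpMRI (34, 17), PSMA-PET
#' (25, 18), mpMRI-or-PET (42, 22) and PSAD-and-mpMRI (20, 12).
#'
#' These margins pin down the joint mpMRI x PET cells by
#' inclusion-exclusion: among the 26 csPCa cases 13 are positive on both
#' imaging tests, 4 mpMRI-only, 5 PET-only and 4 on neither; among the 104
#' patients without csPCa the false-positive cells are 4 both, 13
#' mpMRI-only, 3 PET-only, 84 neither.  PSA-density positivity (61
#' patients, 17 csPCa, 20 of them mpMRI-positive with 12 csPCa) is overlaid
#' by a greedy assignment in a fixed canonical patient order; cells not
#' constrained by the margins are free, and this deterministic completion
#' freezes one consistent choice.  PSA-density values sit at least 0.01
#' away from the 0.15 threshold, so the strict-inequality rule is
#' unambiguous.  An internal consistency check verifies every margin at
#' build time.
#'
#' @return A validated `cohort` data frame of 130 rows.
#' @export
fixture_cohort <- function() {
  # (cspca, mri+, pet+) cell counts, canonical order.
  cells <- data.frame(
    cspca = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    mri = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    pet = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    count = c(13L, 4L, 5L, 4L, 4L, 13L, 3L, 84L),
    # PSAD-positive patients within each cell, greedy completion:
    # csPCa PSAD+ = 17 with 12 among mpMRI+; benign PSAD+ = 44 with 8
    # among mpMRI+.
    n_psad_pos = c(12L, 0L, 5L, 0L, 4L, 4L, 3L, 33L)
  )

  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$count[i]
    data.frame(
      cspca = rep(cells$cspca[i], k),
      mri = rep(cells$mri[i], k),
      pet = rep(cells$pet[i], k),
      psad_pos = seq_len(k) <= cells$n_psad_pos[i]
    )
  }))
  n <- nrow(rows)

  cycle <- function(values, m) rep_len(values, m)
  score_pos <- c(3L, 4L, 5L)
  score_neg <- c(1L, 2L)
  psad_hi <- c(0.18, 0.22, 0.26, 0.31, 0.37)
  psad_lo <- c(0.05, 0.07, 0.09, 0.11, 0.13)

  pirads <- integer(n); primary <- integer(n)
  pirads[rows$mri] <- cycle(score_pos, sum(rows$mri))
  pirads[!rows$mri] <- cycle(score_neg, sum(!rows$mri))
  primary[rows$pet] <- cycle(score_pos, sum(rows$pet))
  primary[!rows$pet] <- cycle(score_neg, sum(!rows$pet))

  psad <- numeric(n)
  psad[rows$psad_pos] <- cycle(psad_hi, sum(rows$psad_pos))
  psad[!rows$psad_pos] <- cycle(psad_lo, sum(!rows$psad_pos))

  isup <- integer(n)
  isup[rows$cspca] <- cycle(c(2L, 3L, 4L, 5L), sum(rows$cspca))
  isup[!rows$cspca] <- cycle(c(0L, 0L, 0L, 1L), sum(!rows$cspca))

  cohort <- as_cohort(data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    psad = psad, pirads = pirads, primary_score = primary, isup = isup,
    stringsAsFactors = FALSE
  ))

  # Build-time consistency check against the target margins.
  target <- list(biopsy_all = c(130L, 26L), psad = c(61L, 17L),
                 mpmri = c(34L, 17L), pet = c(25L, 18L),
                 mpmri_or_pet = c(42L, 22L), psad_and_mpmri = c(20L, 12L))
  for (s in builtin_strategies()) {
    ct <- contingency(cohort, s)
    got <- c(ct$tp + ct$fp, ct$tp)
    if (!identical(got, target[[s$name]])) {
      stop("internal error: reference cohort margin mismatch for '",
           s$name, "' (got ", paste(got, collapse = "/"), ")")
    }
  }
  cohort
}

#' Performance specification for the stochastic cohort simulator
#'
#' Describes the generative model [simulate_cohort()] draws from: csPCa
#' status is Bernoulli(`prevalence`); conditional on status, mpMRI and PET
#' positivity follow a dependent bivariate Bernoulli with the given
#' marginal sensitivities/specificities and joint-positivity
#' probabilities; PSA-density positivity is drawn independently of the
#' imaging tests given status; a continuous PSA density consistent with
#' its binary positivity is then generated from two shifted lognormal
#' families straddling the 0.15 ng/mL/cc threshold.
#'
#' Defaults reproduce the operating characteristics of the 130-patient
#' reference cohort: prevalence 26/130; sensitivities mpMRI 17/26, PET
#' 18/26, PSAD 17/26; specificities mpMRI 87/104, PET 97/104, PSAD
#' 60/104; joint mpMRI-and-PET positivity 13/26 among csPCa and 4/104
#' among benign (a positive dependence: independence would give 11.8/26
#' and 1.1/104).
#'
#' @param prevalence csPCa prevalence in (0, 1) (0 and 1 allowed for
#'   degenerate cohorts).
#' @param sens named numeric: sensitivity of `mpmri`, `pet`, `psad`.
#' @param spec named numeric: specificity of `mpmri`, `pet`, `psad`.
#' @param joint_mri_pet named numeric `c(cspca =, benign =)`: probability
#'   that *both* imaging tests are positive, conditional on disease
#'   status.  Must lie within the Frechet bounds implied by the marginals;
#'   an infeasible value raises an error stating the feasible range.
#' @return Object of class `performance_spec`.
#' @export
performance_spec <- function(prevalence = 26 / 130,
                             sens = c(mpmri = 17 / 26, pet = 18 / 26,
                                      psad = 17 / 26),
                             spec = c(mpmri = 87 / 104, pet = 97 / 104,
                                      psad = 60 / 104),
                             joint_mri_pet = c(cspca = 13 / 26,
                                               benign = 4 / 104)) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  for (nm in c("mpmri", "pet", "psad")) {
    if (!nm %in% names(sens) || !nm %in% names(spec)) {
      stop("sens and spec must name mpmri, pet and psad")
    }
  }
  check_joint <- function(p11, p1, p2, what) {
    lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
    if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
      stop(sprintf(
        "infeasible joint_mri_pet[%s] = %.4f: feasible range [%.4f, %.4f]",
        what, p11, lo, hi))
    }
  }
  check_joint(joint_mri_pet[["cspca"]], sens[["mpmri"]], sens[["pet"]],
              "cspca")
  check_joint(joint_mri_pet[["benign"]], 1 - spec[["mpmri"]],
              1 - spec[["pet"]], "benign")
  structure(
    list(prevalence = prevalence, sens = sens, spec = spec,
         joint_mri_pet = joint_mri_pet),
    class = "performance_spec"
  )
}

# Joint distribution over the 8 (cspca, mri, pet) cells implied by a
# performance_spec, plus PSAD positivity probability by status.
joint_cells <- function(spec) {
  cell4 <- function(p1, p2, p11) {
    c(both = p11, mri_only = p1 - p11, pet_only = p2 - p11,
      neither = 1 - p1 - p2 + p11)
  }
  dis <- cell4(spec$sens[["mpmri"]], spec$sens[["pet"]],
               spec$joint_mri_pet[["cspca"]])
  ben <- cell4(1 - spec$spec[["mpmri"]], 1 - spec$spec[["pet"]],
               spec$joint_mri_pet[["benign"]])
  data.frame(
    cspca = rep(c(TRUE, FALSE), each = 4),
    mri = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
    pet = rep(c(TRUE, FALSE, TRUE, FALSE), 2),
    prob = c(spec$prevalence * dis, (1 - spec$prevalence) * ben),
    psad_pos_prob = rep(c(spec$sens[["psad"]], 1 - spec$spec[["psad"]]),
                        each = 4)
  )
}

# Continuous PSA density consistent with binary positivity: positives are
# 0.15 plus a lognormal excess; negatives are 0.15 shrunk by a lognormal
# factor, so both families stay strictly on their side of the threshold.
draw_psad <- function(positive) {
  n <- length(positive)
  out <- numeric(n)
  np <- sum(positive)
  out[positive] <- 0.15 +
    stats::rlnorm(np, meanlog = log(0.08), sdlog = 0.6)
  out[!positive] <- 0.15 /
    (1 + stats::rlnorm(n - np, meanlog = log(0.5), sdlog = 0.6))
  out
}

#' Simulate a stochastic patient cohort
#'
#' Draws `n` patients from the generative model described by a
#' [performance_spec()]: disease status, dependent mpMRI/PET positivity,
#' independent PSA-density positivity, continuous PSA density, integer
#' PI-RADS and PRIMARY scores (positive scores uniform on 3-5, negative on
#' 1-2), and ISUP grade group (2-5 for csPCa, 0-1 otherwise).
#'
#' @param n number of patients.
#' @param spec a [performance_spec()].
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return A validated `cohort` data frame of `n` rows.
#' @export
simulate_cohort <- function(n, spec = performance_spec(), seed = 1) {
  stopifnot(n > 0, inherits(spec, "performance_spec"))
  set.seed(seed)
  cells <- joint_cells(spec)
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$prob)
  cspca <- cells$cspca[idx]
  mri <- cells$mri[idx]
  pet <- cells$pet[idx]
  psad_pos <- stats::runif(n) < cells$psad_pos_prob[idx]

  rand_score <- function(pos) {
    ifelse(pos, sample(3:5, length(pos), replace = TRUE),
           sample(1:2, length(pos), replace = TRUE))
  }
  isup <- ifelse(cspca, sample(2:5, n, replace = TRUE),
                 sample(0:1, n, replace = TRUE, prob = c(0.75, 0.25)))

  as_cohort(data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    psad = draw_psad(psad_pos),
    pirads = rand_score(mri),
    primary_score = rand_score(pet),
    isup = as.integer(isup),
    stringsAsFactors = FALSE
  ))
}

#' Expected per-patient operating characteristics of the built-in strategies
#'
#' Closed-form expectations under the generative model of a
#' [performance_spec()], obtained by enumerating the 16-cell joint
#' distribution of (csPCa, PSAD positivity, mpMRI positivity, PET
#' positivity) and weighting each cell's per-patient detection indicator
#' and cost ledger.  Used as ground truth when checking the sampling
#' properties of estimators on simulated cohorts.
#'
#' @param spec a [performance_spec()].
#' @param costs a [unit_costs()] object.
#' @param paradigm `"stepwise"` or `"universal"`.
#' @return Data frame with one row per built-in strategy: expected
#'   per-patient probability of referral (`e_referred`), of detected
#'   csPCa (`e_detected`), and expected per-patient cost in EUR
#'   (`e_cost`).
#' @export
strategy_expectations <- function(spec = performance_spec(),
                                  costs = unit_costs(),
                                  paradigm = c("stepwise", "universal")) {
  paradigm <- match.arg(paradigm)
  cells <- joint_cells(spec)
  # Expand to 16 cells by PSAD positivity.
  full <- rbind(
    transform(cells, psad_pos = TRUE, prob = prob * psad_pos_prob),
    transform(cells, psad_pos = FALSE, prob = prob * (1 - psad_pos_prob))
  )
  # One representative patient per cell; scores/values are any members of
  # the positivity classes since the rules only use the class.
  pseudo <- as_cohort(data.frame(
    patient_id = sprintf("C%02d", seq_len(nrow(full))),
    psad = ifelse(full$psad_pos, 0.30, 0.05),
    pirads = ifelse(full$mri, 4L, 1L),
    primary_score = ifelse(full$pet, 4L, 1L),
    isup = ifelse(full$cspca, 2L, 0L),
    stringsAsFactors = FALSE
  ))
  out <- do.call(rbind, lapply(builtin_strategies(), function(s) {
    ref <- refers(s, pseudo)
    cost <- patient_costs(pseudo, s, paradigm, costs)
    data.frame(strategy = s$name,
               e_referred = sum(full$prob * ref),
               e_detected = sum(full$prob * (ref & full$cspca)),
               e_cost = sum(full$prob * cost),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
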