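#' Test utilisation of a strategy under a cost-allocation paradigm
#'
#' Counts how many of each procedure a strategy incurs on a cohort.
#'
#' Under **stepwise** allocation, downstream tests are billed only for
#' patients who reach that step of the clinical pathway (every patient has
#' a PSA assay; imaging counts follow the strategy's pathway, see
#' [builtin_strategies()]).  Under **universal** allocation — a sensitivity
#' analysis — every test the strategy consults is performed in every
#' patient, irrespective of upstream results.  In both paradigms each
#' referred patient incurs one biopsy and one pathology examination.
#'
#' @param cohort a `cohort` data frame.
#' @param strategy a [triage_strategy()].
#' @param paradigm `"stepwise"` or `"universal"`.
#' @param costs a [unit_costs()] object (consulted for `psa_multiplier`).
#' @return Object of class `test_utilization`: integer counts `n_psa`,
#'   `n_mpmri`, `n_pet`, `n_biopsy`, `n_pathology`.
#' @export
utilization <- function(cohort, strategy,
                        paradigm = c("stepwise", "universal"),
                        costs = unit_costs()) {
  cohort <- as_cohort(cohort)
  paradigm <- match.arg(paradigm)
  n <- nrow(cohort)
  n_biopsy <- sum(refers(strategy, cohort))

  if (paradigm == "universal" || is.null(strategy$stepwise_counts)) {
    imaging <- list(
      n_mpmri = if ("mpmri" %in% strategy$required_tests) n else 0L,
      n_pet = if ("pet" %in% strategy$required_tests) n else 0L
    )
  } else {
    imaging <- strategy$stepwise_counts(as.data.frame(cohort))
  }

  structure(
    list(n_psa = n * costs$psa_multiplier,
         n_mpmri = as.integer(imaging$n_mpmri),
         n_pet = as.integer(imaging$n_pet),
         n_biopsy = n_biopsy, n_pathology = n_biopsy),
    class = "test_utilization"
  )
}

#' Total cost of a utilisation profile
#'
#' Sum of count times unit cost over all procedures.  Arithmetic is done
#' in integer cents, so totals are exact; rounding to whole EUR happens
#' only at report time.
#'
#' @param util a `test_utilization` object (or a named list of counts).
#' @param costs a [unit_costs()] object.
#' @return Total cost in EUR (exact, possibly fractional).
#' @export
total_cost <- function(util, costs = unit_costs()) {
  cents <-
    util$n_psa * as_cents(costs$psa) +
    util$n_mpmri * as_cents(costs$mpmri) +
    util$n_pet * as_cents(costs$pet) +
    util$n_biopsy * as_cents(costs$biopsy) +
    util$n_pathology * as_cents(costs$pathology)
  cents_to_eur(cents)
}

#' Cost per csPCa detected
#'
#' @param total total cost in EUR.
#' @param detected number of csPCa detected.
#' @return `total / detected` in EUR, or `NA` when nothing is detected.
#' @export
cost_per_detection <- function(total, detected) {
  stopifnot(detected >= 0)
  ifelse(detected == 0, NA_real_, total / detected)
}

#' Per-patient cost ledger
#'
#' The cost each individual patient incurs under a strategy and paradigm,
#' in EUR.  Summing the ledger over patients equals the utilisation-based
#' [total_cost()] exactly; the ledger is what the paired bootstrap
#' resamples.
#'
#' @inheritParams utilization
#' @return Numeric vector of length `nrow(cohort)`, EUR per patient.
#' @export
patient_costs <- function(cohort, strategy,
                          paradigm = c("stepwise", "universal"),
                          costs = unit_costs()) {
  cohort <- as_cohort(cohort)
  paradigm <- match.arg(paradigm)
  df <- as.data.frame(cohort)
  n <- nrow(df)
  ref <- refers(strategy, cohort)

  has_mri <- "mpmri" %in% strategy$required_tests
  has_pet <- "pet" %in% strategy$required_tests
  if (paradigm == "universal" || is.null(strategy$stepwise_counts)) {
    mri_done <- rep(has_mri, n)
    pet_done <- rep(has_pet, n)
  } else {
    # Mirror the pathway the builtin stepwise counts encode, per patient.
    mri_done <- switch(strategy$name,
      biopsy_all = , psad = , pet = rep(FALSE, n),
      mpmri = , mpmri_or_pet = rep(TRUE, n),
      psad_and_mpmri = pos_psad(df),
      rep(has_mri, n))
    pet_done <- switch(strategy$name,
      biopsy_all = , psad = , mpmri = , psad_and_mpmri = rep(FALSE, n),
      pet = rep(TRUE, n),
      mpmri_or_pet = !pos_mri(df) & pos_pet(df),
      rep(has_pet, n))
  }

  cents <- rep(costs$psa_multiplier * as_cents(costs$psa), n) +
    mri_done * as_cents(costs$mpmri) +
    pet_done * as_cents(costs$pet) +
    ref * (as_cents(costs$biopsy) + as_cents(costs$pathology))
  cents_to_eur(cents)
}

#' Summarise one strategy on a cohort
#'
#' One report row: referral and detection counts, number needed to biopsy,
#' biopsies avoided versus biopsy-all, csPCa missed, diagnostic accuracy
#' metrics, test utilisation, total cost and cost per csPCa detected.
#'
#' @inheritParams utilization
#' @return A one-row data frame.  `total_cost` and `cost_per_cspca` carry
#'   full precision; `total_cost_eur`, `cost_per_cspca_eur` (whole EUR)
#'   and `nnt_1dp` are the display-rounded columns.
#' @export
summarize_strategy <- function(cohort, strategy,
                               costs = unit_costs(),
                               paradigm = c("stepwise", "universal")) {
  cohort <- as_cohort(cohort)
  paradigm <- match.arg(paradigm)
  ct <- contingency(cohort, strategy)
  metrics <- diagnostic_metrics(ct)
  util <- utilization(cohort, strategy, paradigm, costs)
  total <- total_cost(util, costs)
  detected <- ct$tp
  biopsies <- util$n_biopsy
  n_cspca <- ct$tp + ct$fn

  data.frame(
    strategy = strategy$name,
    label = strategy$label,
    biopsies = biopsies,
    cspca_detected = detected,
    nnt = nnt(biopsies, detected),
    nnt_1dp = round_half_up(nnt(biopsies, detected), 1),
    biopsies_avoided = ct$n - biopsies,
    cspca_missed = n_cspca - detected,
    sensitivity = unname(metrics["sensitivity"]),
    specificity = unname(metrics["specificity"]),
    ppv = unname(metrics["ppv"]),
    npv = unname(metrics["npv"]),
    accuracy = unname(metrics["accuracy"]),
    n_psa = util$n_psa,
    n_mpmri = util$n_mpmri,
    n_pet = util$n_pet,
    total_cost = total,
    total_cost_eur = round_half_up(total),
    cost_per_cspca = cost_per_detection(total, detected),
    cost_per_cspca_eur = round_half_up(cost_per_detection(total, detected)),
    stringsAsFactors = FALSE
  )
}

#' Summarise several strategies on a cohort
#'
#' @inheritParams utilization
#' @param strategies list of [triage_strategy()] objects; default the six
#'   built-ins.
#' @return Data frame with one [summarize_strategy()] row per strategy, in
#'   the order given.
#' @export
summarize_strategies <- function(cohort, strategies = builtin_strategies(),
                                 costs = unit_costs(),
                                 paradigm = c("stepwise", "universal")) {
  paradigm <- match.arg(paradigm)
  rows <- lapply(strategies, function(s) {
    summarize_strategy(cohort, s, costs, paradigm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
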