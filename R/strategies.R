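#' Define a biopsy triage strategy
#'
#' A triage strategy is a deterministic binary rule deciding, from a
#' patient's test results, whether the patient is referred to prostate
#' biopsy.  The rule is evaluated vectorised over a cohort; a patient whose
#' rule cannot be evaluated because a required imaging score is missing is
#' classified as *not referred* (conservative), with a warning.
#'
#' `stepwise_counts`, if supplied, returns the number of mpMRI and PET
#' scans actually performed under stepwise allocation, where downstream
#' tests are billed only for patients reaching that step of the pathway.
#' When omitted, stepwise allocation falls back to universal accounting
#' (every test in `required_tests` for every patient), which is the only
#' defensible default for an arbitrary user-defined rule.
#'
#' @param name machine name (snake_case, unique).
#' @param label human-readable label used in reports.
#' @param rule function taking a cohort data frame, returning a logical
#'   vector (`NA` allowed where inputs are missing).
#' @param required_tests character subset of
#'   `c("psa", "psad", "mpmri", "pet")`: the tests the rule consults.
#'   `psad` is derived from the PSA assay and prostate volume and carries
#'   no extra unit cost.
#' @param stepwise_counts optional function taking a cohort data frame and
#'   returning `list(n_mpmri =, n_pet =)`.
#' @return An object of class `triage_strategy`.
#' @export
triage_strategy <- function(name, label, rule, required_tests,
                            stepwise_counts = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(rule))
  extra <- setdiff(required_tests, c("psa", "psad", "mpmri", "pet"))
  if (length(extra)) {
    stop("unknown required_tests: ", paste(extra, collapse = ", "))
  }
  structure(
    list(name = name, label = label, rule = rule,
         required_tests = required_tests, stepwise_counts = stepwise_counts),
    class = "triage_strategy"
  )
}

#' @export
print.triage_strategy <- function(x, ...) {
  cat("Triage strategy '", x$name, "': ", x$label,
      " [tests: ", paste(x$required_tests, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# Positivity helpers with missing treated as not positive (used both by the
# OR/AND rules and by stepwise utilisation counting).
pos_mri <- function(df) !is.na(df$pirads) & df$pirads >= 3L
pos_pet <- function(df) !is.na(df$primary_score) & df$primary_score >= 3L
pos_psad <- function(df) df$psad > 0.15

#' The six built-in triage strategies
#'
#' Returns the six competing biopsy-referral rules evaluated by the
#' package:
#' \describe{
#'   \item{biopsy_all}{biopsy every patient regardless of test results;}
#'   \item{psad}{biopsy if PSA density > 0.15 ng/mL/cc (strict inequality:
#'     a tie at exactly 0.15 is not referred);}
#'   \item{mpmri}{biopsy if mpMRI shows a PI-RADS 3-5 lesion;}
#'   \item{pet}{biopsy if PSMA-PET shows a PRIMARY 3-5 lesion;}
#'   \item{mpmri_or_pet}{biopsy if either imaging test is positive;}
#'   \item{psad_and_mpmri}{biopsy only if PSA density is elevated *and*
#'     mpMRI is positive.}
#' }
#'
#' Stepwise cost accounting follows the clinical pathway each rule
#' implies: under `mpmri_or_pet` every patient undergoes mpMRI and PET is
#' billed only for patients who are mpMRI-negative but PET-positive; under
#' `psad_and_mpmri` every patient undergoes the PSA assay and mpMRI is
#' billed only for patients with elevated PSA density.
#'
#' @return Named list of [triage_strategy()] objects, in report order.
#' @export
builtin_strategies <- function() {
  n_of <- function(df) nrow(df)
  strategies <- list(
    triage_strategy(
      "biopsy_all", "Biopsy-all",
      rule = function(df) rep(TRUE, nrow(df)),
      required_tests = "psa",
      stepwise_counts = function(df) list(n_mpmri = 0L, n_pet = 0L)
    ),
    triage_strategy(
      "psad", "PSAD > 0.15",
      rule = function(df) df$psad > 0.15,
      required_tests = c("psa", "psad"),
      stepwise_counts = function(df) list(n_mpmri = 0L, n_pet = 0L)
    ),
    triage_strategy(
      "mpmri", "mpMRI+ (PI-RADS >= 3)",
      rule = function(df) df$pirads >= 3L,
      required_tests = c("psa", "mpmri"),
      stepwise_counts = function(df) list(n_mpmri = n_of(df), n_pet = 0L)
    ),
    triage_strategy(
      "pet", "PSMA-PET+ (PRIMARY >= 3)",
      rule = function(df) df$primary_score >= 3L,
      required_tests = c("psa", "pet"),
      stepwise_counts = function(df) list(n_mpmri = 0L, n_pet = n_of(df))
    ),
    triage_strategy(
      "mpmri_or_pet", "mpMRI+ OR PET+",
      rule = function(df) (df$pirads >= 3L) | (df$primary_score >= 3L),
      required_tests = c("psa", "mpmri", "pet"),
      stepwise_counts = function(df) {
        list(n_mpmri = n_of(df), n_pet = sum(!pos_mri(df) & pos_pet(df)))
      }
    ),
    triage_strategy(
      "psad_and_mpmri", "PSAD > 0.15 AND mpMRI+",
      rule = function(df) (df$psad > 0.15) & (df$pirads >= 3L),
      required_tests = c("psa", "psad", "mpmri"),
      stepwise_counts = function(df) {
        list(n_mpmri = sum(pos_psad(df)), n_pet = 0L)
      }
    )
  )
  stats::setNames(strategies, vapply(strategies, `[[`, "", "name"))
}

#' Evaluate a strategy's referral rule on a cohort
#'
#' @param strategy a [triage_strategy()].
#' @param cohort a `cohort` data frame.
#' @return Logical vector: `TRUE` where the patient is referred to biopsy.
#'   Patients whose rule is indeterminate because of a missing imaging
#'   score are classified as not referred, with a warning.
#' @export
refers <- function(strategy, cohort) {
  stopifnot(inherits(strategy, "triage_strategy"))
  out <- strategy$rule(as.data.frame(cohort))
  stopifnot(is.logical(out), length(out) == nrow(cohort))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " patient(s) with missing scores classified ",
            "as not referred under strategy '", strategy$name, "'")
    out[is.na(out)] <- FALSE
  }
  out
}

#' 2x2 contingency table of a strategy against the csPCa reference
#'
#' @param cohort a `cohort` data frame.
#' @param strategy a [triage_strategy()].
#' @return Object of class `contingency`: list with counts `tp` (referred,
#'   csPCa), `fp` (referred, no csPCa), `fn` (not referred, csPCa), `tn`
#'   (not referred, no csPCa) and `n`.
#' @export
contingency <- function(cohort, strategy) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  ref <- refers(strategy, cohort)
  dis <- is_cspca(cohort)
  structure(
    list(tp = sum(ref & dis), fp = sum(ref & !dis),
         fn = sum(!ref & dis), tn = sum(!ref & !dis),
         n = nrow(cohort)),
    class = "contingency"
  )
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("referred", "not referred"),
                              c("csPCa", "no csPCa")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive and negative
#' predictive values, and accuracy (tp+tn)/n.  A metric whose denominator
#' is zero (e.g. NPV under a refer-everyone rule) is returned as `NA`.
#'
#' @param table a `contingency` object (or list with tp/fp/fn/tn).
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`, each in \[0, 1\] or `NA` when undefined.
#' @export
diagnostic_metrics <- function(table) {
  with(table, {
    counts <- c(tp, fp, fn, tn)
    if (any(counts < 0)) stop("contingency counts must be nonnegative")
    if (sum(counts) == 0) stop("contingency table is all zero")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    c(sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn),
      accuracy = (tp + tn) / sum(counts))
  })
}

#' Number needed to biopsy
#'
#' Biopsies performed per csPCa detected.  Reported to one decimal in
#' summaries; full precision is returned here.
#'
#' @param biopsies number of biopsies performed.
#' @param detected number of csPCa detected among them.
#' @return `biopsies / detected`, or `NA` when `detected` is zero.
#' @export
nnt <- function(biopsies, detected) {
  stopifnot(biopsies >= detected, detected >= 0)
  ifelse(detected == 0, NA_real_, biopsies / detected)
}
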