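#' Incremental cost-effectiveness ratio
#'
#' ICER = change in cost / change in csPCa detected, for a candidate
#' strategy versus a comparator.  The ratio is only meaningful when the
#' candidate detects strictly more cancers; other sign patterns are
#' returned as a status:
#' \describe{
#'   \item{ratio}{`delta_e > 0`, `delta_c > 0`: EUR per extra csPCa;}
#'   \item{dominant}{`delta_e > 0`, `delta_c <= 0`: more effective and no
#'     more costly — no ratio needed;}
#'   \item{no_delta_effect}{`delta_e = 0`: no detection difference; a
#'     negative `delta_c` means the candidate is cost-saving at equal
#'     effect (weakly dominant);}
#'   \item{less_effective}{`delta_e < 0`: the candidate detects fewer
#'     cancers, so no ratio is reported.}
#' }
#'
#' @param delta_c incremental cost, EUR (candidate minus reference).
#' @param delta_e incremental csPCa detected (candidate minus reference).
#' @return List with `value` (EUR per extra csPCa, full precision; `NA`
#'   unless status is `ratio`), `value_eur` (whole EUR) and `status`.
#' @export
icer <- function(delta_c, delta_e) {
  status <- if (delta_e > 0) {
    if (delta_c > 0) "ratio" else "dominant"
  } else if (delta_e == 0) {
    "no_delta_effect"
  } else {
    "less_effective"
  }
  value <- if (status == "ratio") delta_c / delta_e else NA_real_
  list(value = value, value_eur = round_half_up(value), status = status)
}

#' Incremental net benefit per patient
#'
#' INB = (delta_e x WTP - delta_c) / n: the monetary value of the extra
#' detections at the willingness-to-pay threshold, net of the extra cost,
#' expressed per patient of the cohort.  A positive INB means the
#' candidate strategy is cost-effective versus the comparator at that
#' threshold.
#'
#' @param delta_c incremental cost, EUR (cohort total).
#' @param delta_e incremental csPCa detected (cohort total).
#' @param wtp willingness-to-pay, EUR per csPCa detected; vectorised.
#' @param n cohort size.
#' @return Numeric vector of per-patient INB values (full precision), one
#'   per `wtp`.
#' @export
inb <- function(delta_c, delta_e, wtp, n) {
  if (n <= 0) stop("cohort size n must be positive")
  stopifnot(all(wtp >= 0))
  (delta_e * wtp - delta_c) / n
}

#' Pairwise incremental comparison of strategies against a reference
#'
#' Evaluates every strategy and compares each non-reference strategy with
#' the reference: incremental detections and cost, ICER (or dominance
#' status) and per-patient INB over the willingness-to-pay grid.
#'
#' Incremental costs are computed from the whole-EUR-rounded arm totals —
#' the scale on which cost tables are reported — so that the printed
#' deltas reconcile exactly with the printed totals.
#'
#' @inheritParams summarize_strategies
#' @param reference name of the comparator strategy (default `"mpmri"`,
#'   mpMRI triage at PI-RADS >= 3).
#' @param wtp willingness-to-pay grid, EUR per csPCa detected, strictly
#'   increasing (default 5000, 10000, 20000).
#' @return Data frame with one row per non-reference strategy: `delta_e`,
#'   `delta_c`, `icer`, `icer_status`, and per-patient INB columns
#'   `inb_<wtp>` (whole EUR, half-away-from-zero) with full-precision
#'   twins `inb_raw_<wtp>` and cohort totals `inb_total_<wtp>`.
#' @export
compare_strategies <- function(cohort, strategies = builtin_strategies(),
                               reference = "mpmri",
                               costs = unit_costs(),
                               paradigm = c("stepwise", "universal"),
                               wtp = c(5000, 10000, 20000)) {
  paradigm <- match.arg(paradigm)
  stopifnot(all(wtp > 0), !is.unsorted(wtp, strictly = TRUE))
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  if (!reference %in% names(strategies)) {
    stop("unknown reference strategy: ", reference)
  }
  summary <- summarize_strategies(cohort, strategies, costs, paradigm)
  ref_row <- summary[summary$strategy == reference, ]
  n <- nrow(as_cohort(cohort))

  rows <- lapply(which(summary$strategy != reference), function(i) {
    delta_e <- summary$cspca_detected[i] - ref_row$cspca_detected
    delta_c <- summary$total_cost_eur[i] - ref_row$total_cost_eur
    ic <- icer(delta_c, delta_e)
    inb_raw <- inb(delta_c, delta_e, wtp, n)
    row <- data.frame(
      candidate = summary$strategy[i],
      label = summary$label[i],
      reference = reference,
      n = n,
      delta_e = delta_e,
      delta_c = delta_c,
      icer = ic$value,
      icer_eur = ic$value_eur,
      icer_status = ic$status,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(wtp)) {
      row[[paste0("inb_", wtp[j])]] <- round_half_up(inb_raw[j])
      row[[paste0("inb_raw_", wtp[j])]] <- inb_raw[j]
      row[[paste0("inb_total_", wtp[j])]] <- inb_raw[j] * n
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "wtp") <- wtp
  out
}
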