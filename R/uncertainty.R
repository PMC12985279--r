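#' Uncertainty assumptions for analytic confidence intervals
#'
#' Bundles the standard-error model used by the analytic (Fieller and
#' delta-method) intervals: a binomial variance for the csPCa detection
#' difference and a coefficient-of-variation model for arm-level costs.
#' These analytic SEs are approximate, as conventionally published; the
#' paired bootstrap ([bootstrap_pairwise()]) is the preferred estimator.
#'
#' @param cost_cv coefficient of variation of an arm's total cost,
#'   dimensionless.  Default 0.175, the midpoint of the 15-20% range
#'   typical of diagnostic costing studies.
#' @param cov_ce covariance of incremental cost and incremental effect
#'   (EUR x cases). Default 0; a bootstrap-estimated value may be
#'   injected.
#' @param cov_convention `"algebraic"` applies the minus sign that the
#'   variance algebra of `WTP * dE - dC` yields for `cov(dC, dE)`;
#'   `"as_published"` adds the covariance term with a plus sign, as some
#'   published SE formulas print it.  Identical when `cov_ce = 0`.
#' @param alpha two-sided error rate (default 0.05).
#' @return Object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(cost_cv = 0.175, cov_ce = 0,
                             cov_convention = c("algebraic", "as_published"),
                             alpha = 0.05) {
  stopifnot(cost_cv >= 0, alpha > 0, alpha < 1)
  structure(
    list(cost_cv = cost_cv, cov_ce = cov_ce,
         cov_convention = match.arg(cov_convention), alpha = alpha,
         z = stats::qnorm(1 - alpha / 2)),
    class = "uncertainty_spec"
  )
}

#' Binomial standard error of the detection difference
#'
#' SE of the incremental csPCa count between two strategies evaluated on
#' the same n patients, from a two-arm binomial-difference approximation
#' with common prevalence p: `SE = sqrt(2 p (1 - p) n)` in case counts.
#' The pooled prevalence is used for both arms; no between-arm correlation
#' is assumed (the paired bootstrap captures it empirically).
#'
#' @param p csPCa prevalence, strictly between 0 and 1.
#' @param n cohort size.
#' @return Standard error in csPCa counts.
#' @examples
#' se_delta_effect(26 / 130, 130)  # about 6.45 cases
#' @export
se_delta_effect <- function(p, n) {
  stopifnot(n > 0)
  if (p <= 0 || p >= 1) {
    stop("prevalence p must be strictly between 0 and 1")
  }
  n * sqrt(2 * p * (1 - p) / n)
}

#' Coefficient-of-variation standard error of an arm's cost
#'
#' @param total_cost arm-level total cost, EUR.
#' @param cv coefficient of variation (e.g. 0.175).
#' @return `cv * total_cost`, EUR.
#' @export
se_cost <- function(total_cost, cv) {
  stopifnot(cv >= 0)
  cv * total_cost
}

#' Standard error of an incremental cost from two arm SEs
#'
#' Arm SEs combine in quadrature, `sqrt(se_a^2 + se_b^2)`, when no
#' between-arm covariance is supplied; a known covariance reduces
#' (positive) or inflates (negative) the incremental SE.
#'
#' @param se_a,se_b arm-level cost SEs, EUR.
#' @param cov_ab covariance of the two arm costs (EUR^2), default 0.
#' @return SE of the cost difference, EUR.
#' @export
se_delta_cost <- function(se_a, se_b, cov_ab = 0) {
  v <- se_a^2 + se_b^2 - 2 * cov_ab
  if (v < 0) stop("negative variance: covariance ", cov_ab, " is infeasible")
  sqrt(v)
}

#' Fieller confidence interval for the ICER
#'
#' Classical Fieller bounds for the ratio `delta_c / delta_e` of two
#' (approximately) normal quantities: the confidence set is the set of R
#' with `(dC - R dE)^2 <= z^2 (se_c^2 - 2 R cov + R^2 se_e^2)`, the roots
#' of the quadratic `(dE^2 - z^2 se_e^2) R^2 - 2 (dE dC - z^2 cov) R +
#' (dC^2 - z^2 se_c^2) = 0`.  When the effect difference is not
#' significantly different from zero (`dE^2 - z^2 se_e^2 <= 0`) the set is
#' unbounded: the branch containing the point ratio is reported with the
#' far endpoint infinite, or the whole line when the quadratic has no real
#' roots.  A delta-method interval is returned alongside for diagnostics.
#'
#' @param delta_c incremental cost, EUR.
#' @param delta_e incremental effect, csPCa counts (nonzero).
#' @param se_c,se_e standard errors of `delta_c` and `delta_e`.
#' @param cov covariance of `delta_c` and `delta_e` (EUR x cases).
#' @param alpha two-sided error rate (default 0.05).
#' @return Object of class `interval_estimate`: `point`, `lower`, `upper`
#'   (possibly infinite), `method = "fieller"`, `status` one of
#'   `"bounded"`, `"unbounded"`, `"whole_line"`, `"undefined"`, and
#'   `delta_lower`/`delta_upper` from the delta method.
#' @export
fieller_ci <- function(delta_c, delta_e, se_c, se_e, cov = 0, alpha = 0.05) {
  stopifnot(se_c >= 0, se_e >= 0, delta_e != 0)
  z <- stats::qnorm(1 - alpha / 2)
  point <- delta_c / delta_e

  a <- delta_e^2 - z^2 * se_e^2
  b <- delta_e * delta_c - z^2 * cov
  cc <- delta_c^2 - z^2 * se_c^2
  disc <- b^2 - a * cc

  # Delta-method companion on the log of nothing fancy: first-order SE of
  # the ratio, symmetric around the point.
  var_ratio <- if (se_c == 0 && se_e == 0) 0 else {
    point^2 * (se_c^2 / delta_c^2 + se_e^2 / delta_e^2 -
                 2 * cov / (delta_c * delta_e))
  }
  d_half <- if (is.finite(var_ratio) && var_ratio >= 0) {
    z * sqrt(var_ratio)
  } else NA_real_

  res <- list(point = point, method = "fieller", alpha = alpha,
              delta_lower = point - d_half, delta_upper = point + d_half)

  if (a > 0) {
    if (disc < 0) {
      res$lower <- NA_real_; res$upper <- NA_real_
      res$status <- "undefined"
    } else {
      res$lower <- (b - sqrt(disc)) / a
      res$upper <- (b + sqrt(disc)) / a
      res$status <- "bounded"
    }
  } else if (disc > 0) {
    # a <= 0 with real roots: the set is the complement of an interval;
    # report the branch containing the point estimate.
    r <- sort(c((b - sqrt(disc)) / a, (b + sqrt(disc)) / a))
    if (point >= r[2]) {
      res$lower <- r[2]; res$upper <- Inf
    } else {
      res$lower <- -Inf; res$upper <- r[1]
    }
    res$status <- "unbounded"
  } else {
    res$lower <- -Inf; res$upper <- Inf
    res$status <- "whole_line"
  }
  class(res) <- "interval_estimate"
  res
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s %s interval: point %.1f, (%.1f; %s)%s\n",
              format(100 * (1 - x$alpha)), x$method, x$point, x$lower,
              if (is.finite(x$upper)) sprintf("%.1f", x$upper) else "Inf",
              if (!is.null(x$status)) paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Delta-method confidence interval for the per-patient INB
#'
#' Symmetric interval `INB +/- z * SE_INB / n` around the per-patient
#' incremental net benefit, with the SE computed on the cohort-total scale
#' as `sqrt(se_c^2 + (wtp * se_e)^2 +/- 2 wtp cov)`; the sign of the
#' covariance term follows the configured `cov_convention` (see
#' [uncertainty_spec()]).
#'
#' @inheritParams inb
#' @param se_c SE of the incremental cost (cohort total), EUR.
#' @param se_e SE of the incremental effect, csPCa counts.
#' @param spec an [uncertainty_spec()]; supplies covariance, its sign
#'   convention and the error rate.
#' @return Object of class `interval_estimate` with `method = "delta"`;
#'   vectorised over `wtp` (a list is returned for multiple thresholds).
#' @export
inb_ci <- function(delta_c, delta_e, wtp, n, se_c, se_e,
                   spec = uncertainty_spec()) {
  stopifnot(inherits(spec, "uncertainty_spec"), n > 0)
  one <- function(w) {
    cov_term <- 2 * w * spec$cov_ce
    v <- se_c^2 + (w * se_e)^2 +
      if (spec$cov_convention == "algebraic") -cov_term else cov_term
    if (v < 0) {
      stop("negative INB variance: covariance cov_ce = ", spec$cov_ce,
           " is infeasible under the ", spec$cov_convention, " convention")
    }
    point <- inb(delta_c, delta_e, w, n)
    half <- spec$z * sqrt(v) / n
    structure(list(point = point, lower = point - half,
                   upper = point + half, method = "delta",
                   alpha = spec$alpha, wtp = w, status = "bounded"),
              class = "interval_estimate")
  }
  if (length(wtp) == 1L) one(wtp) else lapply(wtp, one)
}

#' Paired patient-level bootstrap for a pairwise comparison
#'
#' Resamples patients with replacement and re-evaluates *both* strategies
#' on each replicate cohort, preserving the within-patient correlation
#' between arms (each patient contributes their own detection indicator
#' and cost ledger entry to both arms).  Per replicate the incremental
#' effect, incremental cost (whole-EUR-rounded arm totals, as in
#' [compare_strategies()]) and per-patient INB over the WTP grid are
#' recomputed; percentile intervals and the cost-effectiveness
#' acceptability curve (CEAC: the fraction of replicates with INB > 0)
#' are derived from the replicate distribution.
#'
#' Replicates with a zero incremental effect contribute no ICER draw;
#' their proportion is reported as `prop_zero_delta_e`.
#'
#' @inheritParams compare_strategies
#' @param candidate,reference names of the two strategies to compare.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed; identical `seed` and `B` give bit-identical
#'   output.
#' @param indices optional `n x B` integer matrix of resampled patient
#'   indices, overriding the RNG (used for deterministic diagnostics; a
#'   column containing each patient exactly once reproduces the point
#'   estimates).
#' @return Object of class `pairwise_boot`: point estimates, replicate
#'   draws (`delta_e`, `delta_c`, `inb` matrix), percentile intervals for
#'   ICER and INB, `ceac` per WTP, `prop_zero_delta_e`, and the seed.
#' @export
bootstrap_pairwise <- function(cohort, candidate, reference,
                               strategies = builtin_strategies(),
                               costs = unit_costs(),
                               paradigm = c("stepwise", "universal"),
                               wtp = c(5000, 10000, 20000),
                               B = 2000, seed = 1, indices = NULL) {
  cohort <- as_cohort(cohort)
  paradigm <- match.arg(paradigm)
  stopifnot(B >= 1)
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  for (nm in c(candidate, reference)) {
    if (!nm %in% names(strategies)) stop("unknown strategy: ", nm)
  }
  n <- nrow(cohort)
  cand <- strategies[[candidate]]
  ref <- strategies[[reference]]

  # Per-patient contributions: detection indicator and cost ledger per arm.
  e_cand <- refers(cand, cohort) & is_cspca(cohort)
  e_ref <- refers(ref, cohort) & is_cspca(cohort)
  c_cand <- patient_costs(cohort, cand, paradigm, costs)
  c_ref <- patient_costs(cohort, ref, paradigm, costs)

  point_de <- sum(e_cand) - sum(e_ref)
  point_dc <- round_half_up(sum(c_cand)) - round_half_up(sum(c_ref))
  point_inb <- inb(point_dc, point_de, wtp, n)

  if (is.null(indices)) {
    set.seed(seed)
    W <- stats::rmultinom(B, size = n, prob = rep(1, n))
  } else {
    stopifnot(nrow(indices) == n)
    B <- ncol(indices)
    W <- vapply(seq_len(B), function(b) tabulate(indices[, b], nbins = n),
                integer(n))
  }

  de <- as.vector(crossprod(W, e_cand - e_ref))
  dc <- round_half_up(as.vector(crossprod(W, c_cand))) -
    round_half_up(as.vector(crossprod(W, c_ref)))
  inb_draws <- outer(de, wtp) - dc        # cohort-total scale
  inb_draws <- inb_draws / n
  colnames(inb_draws) <- paste0("wtp_", wtp)

  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  icer_draws <- dc[de != 0] / de[de != 0]
  icer_ci <- if (length(icer_draws)) pct(icer_draws) else c(NA_real_, NA_real_)

  inb_ci <- t(apply(inb_draws, 2, pct))
  colnames(inb_ci) <- c("lower", "upper")

  structure(
    list(candidate = candidate, reference = reference, n = n, B = B,
         seed = if (is.null(indices)) seed else NA_integer_,
         wtp = wtp,
         point = list(delta_e = point_de, delta_c = point_dc,
                      inb = stats::setNames(point_inb, paste0("wtp_", wtp))),
         draws = list(delta_e = de, delta_c = dc, inb = inb_draws),
         icer_ci = icer_ci,
         inb_ci = inb_ci,
         ceac = apply(inb_draws, 2, function(x) mean(x > 0)),
         prop_zero_delta_e = mean(de == 0)),
    class = "pairwise_boot"
  )
}

#' @export
print.pairwise_boot <- function(x, ...) {
  cat("Paired bootstrap:", x$candidate, "vs", x$reference,
      "| B =", x$B, "| seed =", x$seed, "\n")
  cat(sprintf("  point: delta_e = %+d, delta_c = %+.0f EUR\n",
              x$point$delta_e, x$point$delta_c))
  for (j in seq_along(x$wtp)) {
    cat(sprintf("  WTP %6d: INB %+7.1f (%.1f; %.1f)  CEAC %.3f\n",
                x$wtp[j], x$point$inb[j], x$inb_ci[j, 1], x$inb_ci[j, 2],
                x$ceac[j]))
  }
  invisible(x)
}
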