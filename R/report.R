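#' Format an EUR amount for display
#'
#' Plain integer string by default; under the `"eu"` locale thousands are
#' separated with dots (the dialect of many European cost tables, e.g.
#' `116058` prints as `"116.058"`).  A true minus sign (U+2212) can be
#' requested for negative amounts.
#'
#' @param value numeric EUR amount(s); rounded half away from zero to
#'   whole EUR before formatting.
#' @param locale `"plain"` or `"eu"`.
#' @param true_minus use U+2212 instead of the ASCII hyphen-minus.
#' @return Character vector.
#' @examples
#' format_eur(116058, "eu")  # "116.058"
#' @export
format_eur <- function(value, locale = c("plain", "eu"),
                       true_minus = FALSE) {
  locale <- match.arg(locale)
  stopifnot(all(is.finite(value) | is.na(value)))
  v <- round_half_up(value)
  # integers only, so the dotted thousands separator is unambiguous
  out <- suppressWarnings(
    formatC(abs(v), format = "d",
            big.mark = if (locale == "eu") "." else ""))
  minus <- if (true_minus) "−" else "-"
  ifelse(is.na(v), NA_character_, ifelse(v < 0, paste0(minus, out), out))
}

#' Configuration for a full triage cost-effectiveness analysis
#'
#' @param cohort a `cohort` data frame, or `NULL` to use the
#'   deterministic [fixture_cohort()].
#' @param costs a [unit_costs()] object.
#' @param paradigm cost-allocation paradigm, `"stepwise"` or
#'   `"universal"`.
#' @param reference comparator strategy name.
#' @param wtp willingness-to-pay grid, EUR per csPCa detected.
#' @param unc an [uncertainty_spec()].
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param out_dir output directory for the report bundle.
#' @param locale display locale for [format_eur()].
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL, costs = unit_costs(),
                            paradigm = c("stepwise", "universal"),
                            reference = "mpmri",
                            wtp = c(5000, 10000, 20000),
                            unc = uncertainty_spec(),
                            bootstrap_B = 2000, seed = 1,
                            out_dir = "results", locale = "plain") {
  structure(
    list(cohort = cohort, costs = costs, paradigm = match.arg(paradigm),
         reference = reference, wtp = wtp, unc = unc,
         bootstrap_B = bootstrap_B, seed = seed, out_dir = out_dir,
         locale = locale),
    class = "analysis_config"
  )
}

#' Run the full analysis and write a report bundle
#'
#' Pipeline: evaluate the six built-in strategies on the cohort
#' (classification, diagnostic metrics, utilisation, costs), compare each
#' against the reference (ICER, INB), attach analytic Fieller/delta
#' intervals, optionally run the paired bootstrap for every comparison,
#' and write `strategy_summary.csv`, `pairwise.csv`, `ceac.csv`, a
#' markdown report and a log (seed and configuration echoed) into the
#' output directory.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, a list with the computed `summary`, `pairwise`,
#'   `ceac` tables and the output paths.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  cohort <- if (is.null(config$cohort)) fixture_cohort() else
    as_cohort(config$cohort)
  n <- nrow(cohort)
  n_cspca <- sum(is_cspca(cohort))
  prev <- n_cspca / n
  say("cohort: n = ", n, ", csPCa = ", n_cspca,
      " (prevalence ", signif(prev, 3), ")")
  if (config$costs$psa_multiplier != 1) {
    warning("psa_multiplier = ", config$costs$psa_multiplier,
            ": strategy totals include repeated PSA assays per patient")
  }

  strategies <- builtin_strategies()
  summary <- summarize_strategies(cohort, strategies, config$costs,
                                  config$paradigm)
  say("evaluated ", nrow(summary), " strategies under ", config$paradigm,
      " allocation")

  pairwise <- compare_strategies(cohort, strategies, config$reference,
                                 config$costs, config$paradigm, config$wtp)
  say("pairwise comparisons vs '", config$reference, "': ", nrow(pairwise))

  # Analytic intervals from the published-style SE model.
  se_e <- if (prev > 0 && prev < 1) se_delta_effect(prev, n) else NA_real_
  ref_cost <- summary$total_cost[summary$strategy == config$reference]
  pairwise$fieller_lower <- NA_real_
  pairwise$fieller_upper <- NA_real_
  for (w in config$wtp) {
    pairwise[[paste0("inb_", w, "_lower")]] <- NA_real_
    pairwise[[paste0("inb_", w, "_upper")]] <- NA_real_
  }
  for (i in seq_len(nrow(pairwise))) {
    cand_cost <- summary$total_cost[summary$strategy ==
                                      pairwise$candidate[i]]
    se_dc <- se_delta_cost(se_cost(cand_cost, config$unc$cost_cv),
                           se_cost(ref_cost, config$unc$cost_cv))
    if (pairwise$delta_e[i] != 0 && is.finite(se_e)) {
      fi <- fieller_ci(pairwise$delta_c[i], pairwise$delta_e[i],
                       se_dc, se_e, config$unc$cov_ce, config$unc$alpha)
      pairwise$fieller_lower[i] <- fi$lower
      pairwise$fieller_upper[i] <- fi$upper
    }
    if (is.finite(se_e)) {
      for (w in config$wtp) {
        ci <- inb_ci(pairwise$delta_c[i], pairwise$delta_e[i], w, n,
                     se_dc, se_e, config$unc)
        pairwise[[paste0("inb_", w, "_lower")]][i] <- ci$lower
        pairwise[[paste0("inb_", w, "_upper")]][i] <- ci$upper
      }
    }
  }

  ceac <- NULL
  if (config$bootstrap_B > 0) {
    boots <- lapply(pairwise$candidate, function(cand) {
      bootstrap_pairwise(cohort, cand, config$reference, strategies,
                         config$costs, config$paradigm, config$wtp,
                         B = config$bootstrap_B, seed = config$seed)
    })
    ceac <- do.call(rbind, lapply(boots, function(b) {
      data.frame(candidate = b$candidate, reference = b$reference,
                 wtp = b$wtp, ceac = unname(b$ceac),
                 inb_boot_lower = b$inb_ci[, "lower"],
                 inb_boot_upper = b$inb_ci[, "upper"],
                 prop_zero_delta_e = b$prop_zero_delta_e,
                 stringsAsFactors = FALSE)
    }))
    rownames(ceac) <- NULL
    say("bootstrap: B = ", config$bootstrap_B, ", seed = ", config$seed)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    summary = file.path(config$out_dir, "strategy_summary.csv"),
    pairwise = file.path(config$out_dir, "pairwise.csv"),
    report = file.path(config$out_dir, "report.md"),
    log = file.path(config$out_dir, "run.log"),
    config = file.path(config$out_dir, "config.json")
  )
  utils::write.csv(summary, paths$summary, row.names = FALSE)
  utils::write.csv(pairwise, paths$pairwise, row.names = FALSE)
  if (!is.null(ceac)) {
    paths$ceac <- file.path(config$out_dir, "ceac.csv")
    utils::write.csv(ceac, paths$ceac, row.names = FALSE)
  }
  writeLines(report_markdown(summary, pairwise, ceac, config), paths$report)

  cfg_json <- list(
    paradigm = config$paradigm, reference = config$reference,
    wtp = config$wtp, bootstrap_B = config$bootstrap_B,
    seed = config$seed, locale = config$locale,
    unit_costs = config$costs[c("psa", "mpmri", "pet", "biopsy",
                                "pathology", "psa_multiplier")],
    uncertainty = config$unc[c("cost_cv", "cov_ce", "cov_convention",
                               "alpha")],
    cohort = if (is.null(config$cohort)) "fixture" else "user-supplied",
    n = n, n_cspca = n_cspca
  )
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("report bundle written to ", normalizePath(config$out_dir),
      " in ", sprintf("%.2f s", as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, paths$log)

  invisible(list(summary = summary, pairwise = pairwise, ceac = ceac,
                 paths = paths))
}

# Markdown rendering of the three tables; pure formatting, every number is
# taken from the computed data frames.
report_markdown <- function(summary, pairwise, ceac, config) {
  eur <- function(x) format_eur(x, config$locale)
  md_table <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) {
      paste0("| ", paste(trimws(r), collapse = " | "), " |")
    })
    c(header, sep, body)
  }

  tab2 <- data.frame(
    Strategy = summary$label,
    Biopsies = summary$biopsies,
    csPCa = summary$cspca_detected,
    NNT = sprintf("%.1f", summary$nnt_1dp),
    `Biopsies avoided` = summary$biopsies_avoided,
    `csPCa missed` = summary$cspca_missed,
    `Total cost (EUR)` = eur(summary$total_cost_eur),
    `Cost per csPCa (EUR)` = eur(summary$cost_per_cspca_eur),
    check.names = FALSE
  )
  icer_label <- ifelse(
    pairwise$icer_status == "ratio", eur(pairwise$icer_eur),
    ifelse(pairwise$icer_status == "no_delta_effect",
           ifelse(pairwise$delta_c < 0, "no Δ effect (cost-saving)",
                  "no Δ effect"),
           ifelse(pairwise$icer_status == "less_effective",
                  "N/A (less eff.)", "dominant")))
  tab34 <- data.frame(
    Strategy = pairwise$label,
    `ΔcsPCa` = sprintf("%+d", pairwise$delta_e),
    `ΔCost (EUR)` = eur(pairwise$delta_c),
    `ICER (EUR/csPCa)` = icer_label,
    check.names = FALSE
  )
  for (w in attr(pairwise, "wtp")) {
    tab34[[paste0("INB ", eur(w))]] <- eur(pairwise[[paste0("inb_", w)]])
  }

  lines <- c(
    "# Biopsy triage cost-effectiveness report", "",
    paste0("Paradigm: ", config$paradigm, "; reference: ",
           config$reference, "; seed: ", config$seed),
    "", "## Strategy summary", "", md_table(tab2),
    "", paste0("## Pairwise comparison vs ", config$reference), "",
    md_table(tab34))
  if (!is.null(ceac)) {
    tabc <- data.frame(
      Candidate = ceac$candidate, WTP = eur(ceac$wtp),
      CEAC = sprintf("%.3f", ceac$ceac), check.names = FALSE
    )
    lines <- c(lines, "", "## Cost-effectiveness acceptability", "",
               md_table(tabc))
  }
  lines
}
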