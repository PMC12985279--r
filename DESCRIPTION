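Package: biopsycea
Title: Cost-Effectiveness Analysis of Prostate Biopsy Triage Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates binary biopsy-referral (triage) strategies for the
    detection of clinically significant prostate cancer (ISUP grade group
    >= 2) on patient-level cohorts combining PSA density, mpMRI (PI-RADS)
    and PSMA-PET (PRIMARY score).  Computes per-strategy contingency
    tables, diagnostic accuracy, number needed to biopsy, and direct
    hospital costs under stepwise or universal test allocation; compares
    strategies by incremental cost-effectiveness ratio (ICER) and
    incremental net benefit (INB) over a willingness-to-pay grid, with
    Fieller confidence intervals for ratios, delta-method intervals for
    net benefits, and a paired patient-level bootstrap with
    cost-effectiveness acceptability curves.  Includes a deterministic
    130-patient reference cohort and a stochastic cohort simulator with
    configurable prevalence, test accuracies and inter-test dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
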