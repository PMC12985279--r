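---
title: "Cost-effectiveness of prostate biopsy triage strategies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of prostate biopsy triage strategies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopsycea)
```

## The problem

Men with persistent clinical suspicion of prostate cancer after a negative
biopsy face a re-biopsy decision. Three tests can triage that decision:
PSA density (PSAD, serum PSA divided by prostate volume, in ng/mL/cc),
multiparametric MRI scored on the PI-RADS 1–5 scale, and PSMA-PET/CT
scored on the PRIMARY 1–5 scale. A *triage strategy* is a binary rule
mapping a patient's test results to a biopsy referral. The reference
standard is clinically significant prostate cancer (csPCa), defined as
ISUP grade group ≥ 2 on biopsy; grade group 1 disease is cancer but not
clinically significant, and we encode a negative biopsy as grade 0.

The package evaluates six competing strategies on a patient-level cohort:
biopsy-all, PSAD > 0.15, mpMRI positive (PI-RADS ≥ 3), PSMA-PET positive
(PRIMARY ≥ 3), the disjunction of the two imaging tests, and the
conjunction of elevated PSAD with positive mpMRI. Thresholds are read
literally: PSAD exactly 0.15 does *not* refer, and imaging positivity is
score ≥ 3 (PET positivity at PRIMARY ≥ 4 is sometimes advocated for
specificity, but ≥ 3 is the rule costed here). A patient whose rule
cannot be evaluated because an imaging score is missing (e.g. a
contraindication to mpMRI) is conservatively classified as not referred,
with a warning; the disjunction can still refer such a patient on the
other test alone.

## Diagnostic evaluation

Each strategy is tabulated against the csPCa reference in a 2×2
contingency table, giving sensitivity, specificity, PPV, NPV and
accuracy; undefined ratios (zero denominators, e.g. NPV when everyone is
referred) are reported as `NA` rather than an arbitrary number. The
number needed to biopsy, NNT = biopsies / csPCa detected, is displayed to
one decimal with full precision retained internally. Missed csPCa are
false negatives counted relative to the biopsy-all strategy, which by
construction detects every case.

## Costing

Unit costs (EUR, institutional reimbursement tariffs): PSA assay 1.55,
mpMRI 283.5, PSMA-PET 938, fusion biopsy 809.4, pathology examination
81.8. Pathology is billed once per biopsy session, not per core. Two
allocation paradigms are implemented:

* **Stepwise** (primary analysis): downstream tests are billed only for
  patients who reach that step of the pathway. Every patient has one PSA
  assay. Under the disjunction, every patient undergoes mpMRI and PET is
  billed only for mpMRI-negative, PET-positive patients — this is the
  stated accounting convention even though one cannot in practice know a
  PET result before scanning; we implement it as the pathway's accounting
  rule and flag the caveat. Under the conjunction, mpMRI is billed only
  for PSAD-elevated patients.
* **Universal** (sensitivity analysis): every test the strategy consults
  is performed in all patients. Universal totals are never below
  stepwise totals, strictly above for the two composite strategies.

The number of PSA assays billed per patient is a configuration knob
(`psa_multiplier`, default 1). Enrolment protocols may require repeated
PSA measurements — some tariff tables list the assay three times — but
the costed diagnostic pathway uses a single assay per patient, and the
per-strategy totals reconcile to the cent only under multiplier 1.

Money is carried internally as integer cents, so totals are exact;
rounding to whole EUR (half away from zero) happens only in report
columns. This matters: the biopsy-all total is exactly 116,057.50 EUR,
which must round up.

## Incremental analysis

For a candidate strategy versus a comparator (default: mpMRI triage),

* ΔE = csPCa detected (candidate − reference),
* ΔC = total cost (candidate − reference), computed from the
  whole-EUR-rounded arm totals so that printed deltas reconcile exactly
  with printed totals,
* ICER = ΔC / ΔE (EUR per extra csPCa), reported only when ΔE > 0 and
  ΔC > 0; other sign patterns are classified as `dominant` (more
  effective, no more costly), `no_delta_effect` (ΔE = 0; with ΔC < 0 the
  candidate is cost-saving at equal effect, i.e. weakly dominant — we do
  not label this "dominated" as some tables do), or `less_effective`
  (ΔE < 0, no ratio reported),
* INB(λ) = (ΔE·λ − ΔC) / n, the incremental net benefit *per patient* at
  willingness-to-pay λ ∈ {5,000; 10,000; 20,000} EUR per csPCa detected.
  The per-patient convention is forced by reconciling the INB formula
  with the reported tables; cohort-total INB is emitted alongside. INB is
  affine in λ with slope ΔE/n, so a strategy with ΔE = 0 has a
  λ-independent INB.

## Uncertainty

Analytic standard errors follow the published convention: the detection
difference gets a two-arm binomial SE on the same n with pooled
prevalence p, SE(ΔE) = √(2·p·(1−p)·n) — 6.45 cases at p = 0.2, n = 130 —
and each arm's cost gets SE = CV × total, CV defaulting to 0.175 (the
midpoint of the 15–20% range typical of diagnostic costing studies),
combined across arms in quadrature unless a covariance is supplied.
These SEs are approximate, as conventionally published; the paired
bootstrap is the preferred estimator.

**Fieller interval for the ICER.** The confidence set for R = ΔC/ΔE is
the set of R satisfying (ΔC − R·ΔE)² ≤ z²(SE_C² − 2R·cov + R²·SE_E²),
i.e. the roots of (ΔE² − z²SE_E²)R² − 2(ΔE·ΔC − z²cov)R +
(ΔC² − z²SE_C²) = 0. When ΔE is not significantly different from zero
(ΔE² ≤ z²SE_E²) the set is unbounded: with real roots it is the
complement of an interval and we report the branch containing the point
estimate with the far endpoint infinite; with no real roots it is the
whole line. With ΔE = 1 against SE 6.45 the upper bound is +∞ — exactly
the shape a one-extra-detection comparison produces. A delta-method
interval is returned alongside for diagnostics.

**Delta-method INB interval.** Symmetric, with SE_INB computed on the
cohort-total scale as √(SE_ΔC² + (λ·SE_ΔE)² ∓ 2λ·cov(ΔC,ΔE)) and divided
by n. The sign of the covariance term is convention-dependent: the
variance algebra of λ·ΔE − ΔC yields a minus sign on cov(ΔC, ΔE), while
some published SE formulas print a plus. Both are available via
`cov_convention` ("algebraic", the default, and "as_published"); they
coincide at the default cov = 0, and neither is asserted as ground truth.

**Paired bootstrap.** Patients are resampled with replacement and *both*
strategies are re-evaluated on each replicate cohort, preserving the
within-patient correlation between arms — each patient contributes their
own detection indicator and cost-ledger entry to both arms. Resampling
is implemented as multinomial replicate weights, distributionally
identical to index resampling and fast enough for thousands of
replicates. Per replicate we recompute ΔE, ΔC and INB over the WTP grid;
percentile intervals and the cost-effectiveness acceptability curve
(CEAC, the fraction of replicates with INB > 0) follow. Replicates with
ΔE = 0 contribute no ICER draw and their proportion is reported. The
default is B = 2000 with a single recorded seed; identical seeds give
bit-identical output.

## Synthetic cohorts

`fixture_cohort()` builds, without RNG, a 130-patient cohort (26 csPCa)
whose per-strategy (biopsied, detected) margins are: biopsy-all
(130, 26), PSAD (61, 17), mpMRI (34, 17), PET (25, 18), disjunction
(42, 22), conjunction (20, 12). Inclusion–exclusion pins the joint
imaging cells: among csPCa, 13 both-positive, 4 mpMRI-only, 5 PET-only,
4 neither; among benign, 4 / 13 / 3 / 84. PSAD positivity (61 total, 17
csPCa, 20 among mpMRI-positives with 12 csPCa) is overlaid by a greedy
assignment in a fixed canonical patient order; joint cells not
constrained by the margins (e.g. the PSAD × PET overlap) are free, and
any consistent completion reproduces every reported number, so one
choice is frozen for reproducibility. PSAD values keep ≥ 0.02 clear of
the 0.15 threshold; ISUP grades cycle deterministically over 2–5 for
csPCa (the grade does not affect anything beyond the ≥ 2 threshold) and
over {0, 0, 0, 1} otherwise. A build-time check verifies every margin.

`simulate_cohort()` draws stochastic cohorts: disease ~
Bernoulli(prevalence); mpMRI and PET positivity from a dependent
bivariate Bernoulli with configurable sensitivities, specificities and
joint-positivity probabilities (defaults reproduce the fixture's
operating characteristics, including its positive inter-test
dependence — independence would give 11.8, not 13, double-positive csPCa
in expectation; infeasible joint probabilities are rejected with the
Fréchet bounds); PSAD positivity independent of imaging given disease
status; continuous PSAD from two shifted lognormal families strictly
straddling 0.15. `strategy_expectations()` gives closed-form per-patient
expected referral, detection and cost for each strategy by enumerating
the 16-cell joint distribution — the ground truth used when checking
estimator calibration on simulated cohorts.

The generator emulates the statistical structure the analysis consumes —
binary positivity with realistic dependence — and nothing else: no PSA
kinetics, prostate volume, age, or lesion-level detail. Passing tests on
simulated cohorts therefore validate the estimators' sampling behaviour
under this structure, not the clinical realism of any particular cohort.

## Validation problem sizes and known limitations

The test suite checks the Fieller implementation against a bivariate
normal Monte-Carlo ratio oracle (20 random bounded configurations, 10⁶
draws each, endpoints within 1%) and the bootstrap's percentile-interval
coverage on 500 simulated 130-patient cohorts (B = 1000, truth from
`strategy_expectations()`).

Known limitations:

* Percentile bootstrap intervals for the per-patient INB slightly
  under-cover at n = 130 (measured ≈ 92–93% for nominal 95%): the
  per-patient INB contribution of the disjunction-vs-mpMRI comparison is
  a three-point distribution with ~94% of its mass at zero — only
  mpMRI-negative/PET-positive patients contribute — and the percentile
  method is known to under-cover for such skewed means at moderate n.
* The analytic Fieller/delta intervals depend on an assumed cost CV and
  cost–effect covariance; with the default cov = 0 they describe interval
  *shape* (bounded vs unbounded) faithfully but their numeric endpoints
  are only as good as those assumptions. Published interval endpoints
  computed under unstated CV/covariance choices are reproduced
  qualitatively, not numerically.
* Stepwise accounting for the disjunction bills PET only for
  mpMRI-negative/PET-positive patients, which is not an operationally
  realizable ordering; it is the stated costing convention of the
  pathway.
* The efficiency frontier across more than two strategies (extended
  dominance) is out of scope; comparisons are strictly pairwise against
  a chosen reference.

## A worked run

```{r example, eval = FALSE}
cohort <- fixture_cohort()
summarize_strategies(cohort)[, c("label", "biopsies", "cspca_detected",
                                 "total_cost_eur", "cost_per_cspca_eur")]
compare_strategies(cohort, reference = "mpmri")[
  , c("candidate", "delta_e", "delta_c", "icer_eur",
      "inb_5000", "inb_10000", "inb_20000")]
bootstrap_pairwise(cohort, "mpmri_or_pet", "mpmri", B = 2000, seed = 1)
```

The numbered scripts under `analysis/` run the full workflow: build the
cohort, evaluate the strategies under both paradigms, compare against
mpMRI, quantify uncertainty, and emit the report bundle.
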