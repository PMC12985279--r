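# Small cohort builders used across test files.

mk_cohort <- function(psad, pirads, primary, isup,
                      id = sprintf("T%02d", seq_along(psad))) {
  as_cohort(data.frame(
    patient_id = id, psad = psad, pirads = pirads,
    primary_score = primary, isup = isup, stringsAsFactors = FALSE
  ))
}

# Three hand-checkable patients: one csPCa caught by both imaging tests,
# one csPCa missed by everything but biopsy-all, one benign MRI false
# positive with elevated PSA density.
tiny_cohort <- function() {
  mk_cohort(psad = c(0.30, 0.10, 0.20),
            pirads = c(5L, 1L, 4L),
            primary = c(4L, 2L, 1L),
            isup = c(3L, 2L, 0L))
}

table2_margins <- list(
  biopsy_all = c(130L, 26L), psad = c(61L, 17L), mpmri = c(34L, 17L),
  pet = c(25L, 18L), mpmri_or_pet = c(42L, 22L),
  psad_and_mpmri = c(20L, 12L)
)
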