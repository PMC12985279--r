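#' Unit costs per procedure
#'
#' Direct hospital reimbursement costs, in EUR, for the single procedures a
#' triage pathway can incur: a PSA assay, an mpMRI scan, a PSMA-PET scan, a
#' fusion-guided prostate biopsy, and the pathology examination of the
#' biopsy material.  Defaults are institutional tariffs under the Italian
#' National Health System.
#'
#' `psa_multiplier` scales the number of PSA assays billed per patient.
#' Protocols that require repeated PSA measurements for enrolment may bill
#' the assay more than once; the costed diagnostic pathway itself uses one
#' assay per patient, so the default is 1.
#'
#' @param psa EUR per PSA assay.
#' @param mpmri EUR per multiparametric MRI.
#' @param pet EUR per PSMA-PET/CT.
#' @param biopsy EUR per fusion-guided biopsy session.
#' @param pathology EUR per pathology examination (one per biopsy session).
#' @param psa_multiplier number of PSA assays billed per patient (default 1).
#' @return An object of class `unit_costs`: a named list of nonnegative
#'   EUR amounts plus the PSA multiplier.
#' @examples
#' costs <- unit_costs()
#' costs$biopsy + costs$pathology  # cost of one biopsy episode
#' @export
unit_costs <- function(psa = 1.55, mpmri = 283.5, pet = 938,
                       biopsy = 809.4, pathology = 81.8,
                       psa_multiplier = 1) {
  vals <- c(psa = psa, mpmri = mpmri, pet = pet,
            biopsy = biopsy, pathology = pathology)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("unit costs must be finite and nonnegative")
  }
  if (!is.finite(psa_multiplier) || psa_multiplier < 0) {
    stop("psa_multiplier must be a nonnegative number")
  }
  structure(
    list(psa = psa, mpmri = mpmri, pet = pet, biopsy = biopsy,
         pathology = pathology, psa_multiplier = psa_multiplier),
    class = "unit_costs"
  )
}

#' @export
print.unit_costs <- function(x, ...) {
  cat("Unit costs (EUR): PSA", x$psa, "| mpMRI", x$mpmri, "| PSMA-PET",
      x$pet, "| biopsy", x$biopsy, "| pathology", x$pathology,
      "| PSA multiplier", x$psa_multiplier, "\n")
  invisible(x)
}

cohort_columns <- c("patient_id", "psad", "pirads", "primary_score", "isup")

#' Construct and validate a patient cohort
#'
#' A cohort is a data frame with one row per patient and columns
#' `patient_id` (unique identifier), `psad` (PSA density, ng/mL/cc),
#' `pirads` (mpMRI PI-RADS score, 1-5 or `NA`), `primary_score` (PSMA-PET
#' PRIMARY score, 1-5 or `NA`) and `isup` (biopsy ISUP grade group, 0-5;
#' 0 encodes a negative/benign biopsy, 1 is cancer that is not clinically
#' significant).  Imaging scores may be missing (e.g. contraindications to
#' mpMRI); PSA density and the biopsy reference standard may not.
#'
#' @param df data frame with the columns above.
#' @return The validated data frame with class `cohort` prepended.
#' @seealso [read_cohort()], [fixture_cohort()], [simulate_cohort()]
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[cohort_columns]
  df$patient_id <- as.character(df$patient_id)

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, paste0(
        what, " in row(s) ", paste(rows, collapse = ", ")))
    }
  }
  note(which(is.na(df$patient_id) | df$patient_id == ""), "empty patient_id")
  note(which(duplicated(df$patient_id)), "duplicate patient_id")
  note(which(is.na(df$psad)), "missing psad")
  note(bad(df$psad < 0), "negative psad")
  note(which(!is.na(df$pirads) & !(df$pirads %in% 1:5)),
       "pirads outside 1-5")
  note(which(!is.na(df$primary_score) & !(df$primary_score %in% 1:5)),
       "primary_score outside 1-5")
  note(which(is.na(df$isup) | !(df$isup %in% 0:5)), "isup outside 0-5")
  if (length(problems)) {
    stop("invalid cohort: ", paste(problems, collapse = "; "))
  }
  df$pirads <- as.integer(df$pirads)
  df$primary_score <- as.integer(df$primary_score)
  df$isup <- as.integer(df$isup)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a patient cohort from a delimited text file
#'
#' @param path path to a delimited text file with a header row and columns
#'   `patient_id`, `psad`, `pirads`, `primary_score`, `isup`.  Empty cells
#'   are treated as missing.
#' @param sep field separator (default comma).
#' @return A validated [as_cohort()] data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop("cohort not found: ", path)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(patient_id = "character"),
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' all field values exactly.
#'
#' @param cohort a `cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Clinically significant prostate cancer (csPCa) reference standard
#'
#' csPCa is defined as ISUP grade group >= 2.  Grade group 0 (negative
#' biopsy) and 1 (insignificant cancer) are not clinically significant.
#'
#' @param x a `cohort` data frame or an integer vector of ISUP grade groups.
#' @return Logical vector, `TRUE` where the biopsy shows csPCa.
#' @examples
#' is_cspca(c(0, 1, 2, 5))
#' @export
is_cspca <- function(x) {
  isup <- if (is.data.frame(x)) x$isup else x
  if (any(is.na(isup))) {
    stop("isup is required to determine csPCa status")
  }
  if (any(!(isup %in% 0:5))) {
    stop("isup must be an integer in 0-5")
  }
  isup >= 2
}

#' @export
print.cohort <- function(x, ...) {
  cat("Patient cohort: n =", nrow(x), "with", sum(is_cspca(x)),
      "csPCa (ISUP >= 2)\n")
  NextMethod()
}
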