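#' Read per-sample clinical and technical metadata from TSV
#'
#' Expected columns: `sample_id`, `cohort` (HV/CLINIC), `diagnosis`
#' (NONE/BENIGN/CANCER/INELIGIBLE), `smoking_status` (NV/FS1/FS2/FS3/CS),
#' `pack_years` (PY1-PY4), `sex` (F/M), `age_class` (ordinal 0-3), `batch`
#' (0/1), `copd` (no/yes/unknown), `tissue` (nasal/bronchial).
#'
#' @param path Path to a tab-separated metadata file.
#' @return A validated tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cohort = readr::col_character(),
    diagnosis = readr::col_character(),
    smoking_status = readr::col_character(),
    pack_years = readr::col_character(),
    sex = readr::col_character(),
    age_class = readr::col_integer(),
    batch = readr::col_integer(),
    copd = readr::col_character(),
    tissue = readr::col_character()
  ), progress = FALSE)
  validate_metadata(meta)
}

#' Write sample metadata to TSV
#'
#' @param metadata Metadata tibble as returned by [read_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' Enforces the categorical vocabularies and the structural invariants:
#' never smokers carry pack-years category PY1, and clinical diagnoses
#' (BENIGN/CANCER/INELIGIBLE) occur only in the clinic cohort.
#'
#' @param metadata Metadata tibble.
#' @return The validated tibble.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "cohort", "diagnosis", "smoking_status", "pack_years",
            "sex", "age_class", "batch", "copd", "tissue")
  missing <- setdiff(need, names(metadata))
  assert_that(length(missing) == 0,
              paste("metadata missing columns:", paste(missing, collapse = ", ")))
  assert_that(!anyDuplicated(metadata$sample_id), "duplicated sample ids in metadata")
  chk <- function(col, levels) {
    bad <- setdiff(unique(metadata[[col]]), levels)
    assert_that(length(bad) == 0, sprintf(
      "invalid %s value(s): %s", col, paste(bad, collapse = ", ")))
  }
  chk("cohort", COHORT_LEVELS)
  chk("diagnosis", DIAGNOSIS_LEVELS)
  chk("smoking_status", SMOKING_LEVELS)
  chk("pack_years", PACK_YEARS_LEVELS)
  chk("sex", c("F", "M"))
  chk("copd", c("no", "yes", "unknown"))
  chk("tissue", c("nasal", "bronchial"))
  assert_that(all(metadata$age_class %in% 0:3), "age_class must be in 0..3")
  assert_that(all(metadata$batch %in% 0:1), "batch must be 0 or 1")
  nv_bad <- metadata$smoking_status == "NV" & metadata$pack_years != "PY1"
  assert_that(!any(nv_bad), "never smokers must have pack_years PY1")
  dx_bad <- metadata$diagnosis %in% c("BENIGN", "CANCER", "INELIGIBLE") &
    metadata$cohort != "CLINIC"
  assert_that(!any(dx_bad),
              "BENIGN/CANCER/INELIGIBLE diagnoses are only valid in the CLINIC cohort")
  tibble::as_tibble(metadata)
}
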