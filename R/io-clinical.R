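clinical_required_cols <- c(
  "patient_id", "histology", "age", "sex", "smoking", "stage",
  "mutation_status", "tc_pct", "ic_pct", "os_months", "event"
)

clinical_vocab <- list(
  histology = c("ADC", "SQCC"),
  sex = c("male", "female"),
  smoking = c("never", "smoker"),
  stage = c("IIIB", "IV"),
  mutation_status = c("EGFR", "KRAS", "other")
)

#' Read and validate a clinical cohort table
#'
#' The clinical CSV schema is defined by this package: one row per
#' patient with `patient_id`, `histology` (ADC/SQCC), `age` (years),
#' `sex` (male/female), `smoking` (never/smoker), `stage` (IIIB/IV),
#' `mutation_status` (EGFR/KRAS/other), `tc_pct` and `ic_pct` (PD-L1
#' staining percentages in `[0,100]`), `os_months` (overall survival,
#' months from therapy start) and `event` (1 = death, 0 = censored at
#' last follow-up). Unknown category labels, negative ages or survival
#' times, and out-of-range percentages are rejected.
#'
#' @param path CSV path.
#' @return validated tibble of patient records.
#' @export
read_clinical <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_clinical(data)
}

#' @rdname read_clinical
#' @param data an in-memory clinical table to validate.
#' @export
validate_clinical <- function(data) {
  check_cols(data, clinical_required_cols, "clinical table")
  if (anyDuplicated(data$patient_id)) abort("duplicate patient_id")
  if (!is.numeric(data$age) || any(is.na(data$age)) || any(data$age < 0)) {
    abort("`age` must be non-negative")
  }
  for (col in names(clinical_vocab)) {
    bad <- setdiff(unique(data[[col]]), clinical_vocab[[col]])
    if (length(bad) > 0) {
      abort(sprintf("unknown %s category: %s", col, paste(bad, collapse = ", ")))
    }
  }
  check_pct(data$tc_pct, "tc_pct")
  check_pct(data$ic_pct, "ic_pct")
  if (!is.numeric(data$os_months) || any(is.na(data$os_months)) ||
      any(data$os_months < 0)) {
    abort("`os_months` must be non-negative survival times")
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("`event` flag must be 0 (censored) or 1 (death)")
  }
  as_tibble(data)
}

#' Write a synthetic cohort to disk
#'
#' Materializes the simulator output in the standard formats consumed by
#' the pipeline: `panel.bed` (0-based half-open), one VCF per patient
#' under `vcf/`, `clinical.csv`, and a `manifest.json` tying the files
#' together with the seed and a hash of the generating configuration.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_panel(cohort$panel, file.path(dir, "panel.bed"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  ids <- cohort$clinical$patient_id
  vcfs <- character(length(ids))
  for (i in seq_along(ids)) {
    v <- filter(cohort$variants, .data$patient_id == ids[i])
    vcfs[i] <- file.path("vcf", paste0(ids[i], ".vcf"))
    write_variants_vcf(v, file.path(dir, vcfs[i]))
  }
  manifest <- list(
    seed = cohort$config$seed,
    config_hash = rlang::hash(unclass(cohort$config)),
    n_patients = nrow(cohort$clinical),
    panel = "panel.bed",
    clinical = "clinical.csv",
    vcf = as.list(setNames(vcfs, ids)),
    territory_mb = panel_territory_mb(cohort$panel)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
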