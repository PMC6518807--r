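#' Published reference summary counts for a 187-patient NSCLC cohort
#'
#' Two small summary tables shipped with the package, reconstructed from
#' the printed results of a published two-histology NSCLC cohort (136
#' adenocarcinoma, 51 squamous):
#'
#' * `driver_alleles`: per-allele subject counts for the EGFR and KRAS
#'   driver mutations (e.g. 33 L858R + 25 exon-19 deletions for EGFR).
#' * `pdl1_categories`: per-histology, per-compartment PD-L1 category
#'   counts. The four-category counts are the unique integer solution
#'   consistent with both the printed integer percentages (half-up
#'   rounding) and the printed negative/any+ subgroup margins.
#'
#' @return list of two tibbles, `driver_alleles` and `pdl1_categories`.
#' @export
reference_cohort_counts <- function() {
  list(
    driver_alleles = readr::read_csv(
      system.file("extdata", "driver_allele_counts.csv", package = "tmbpdl1"),
      show_col_types = FALSE
    ),
    pdl1_categories = readr::read_csv(
      system.file("extdata", "pdl1_category_counts.csv", package = "tmbpdl1"),
      show_col_types = FALSE
    )
  )
}

#' Expand reference PD-L1 category counts into a scorable pseudo-cohort
#'
#' Turns the shipped per-category counts into one row per patient with a
#' representative staining percentage inside each category's bin, so the
#' scoring ladder and frequency-table machinery can recompute the
#' published percentages from scratch.
#'
#' @param histology `"ADC"` or `"SQCC"`.
#' @return tibble with `tc_pct` and `ic_pct` columns.
#' @export
reference_pdl1_cohort <- function(histology = c("ADC", "SQCC")) {
  histology <- arg_match(histology)
  counts <- reference_cohort_counts()$pdl1_categories
  counts <- filter(counts, .data$histology == !!histology)
  # representative percentage in the interior of each category bin
  rep_pct <- list(
    tc = c(negative = 0.5, weak = 2, moderate = 20, strong = 70),
    ic = c(negative = 0.5, weak = 2, moderate = 7, strong = 30)
  )
  expand <- function(comp) {
    cc <- filter(counts, .data$compartment == comp)
    rep(unname(rep_pct[[comp]][cc$category]), cc$count)
  }
  tc <- expand("tc")
  ic <- expand("ic")
  stopifnot(length(tc) == length(ic))
  tibble(tc_pct = tc, ic_pct = ic)
}
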