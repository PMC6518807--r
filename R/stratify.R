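#' Combine dichotomized TMB and PD-L1 positivity into biomarker classes
#'
#' The combined classes are: `LM_neg` (low/moderate TMB + PD-L1
#' negative), `LM_pos` (low/moderate TMB + PD-L1 positive), `H_pos` (high
#' TMB + PD-L1 positive) and `H_neg` (high TMB + PD-L1 negative). The
#' fourth class completes the partition; survival figures conventionally
#' plot only the first three, and [run_full_analysis()] can exclude
#' `H_neg` from the combined-class survival comparison for that reason.
#' PD-L1 positivity in the combination uses TC any+ only.
#'
#' @param tmb_binary factor/character `High` / `Low/Moderate` (see
#'   [dichotomize_tmb()]).
#' @param pdl1_positive logical, PD-L1 TC any-positive.
#' @return factor with levels `LM_neg`, `LM_pos`, `H_pos`, `H_neg`.
#' @examples
#' combine_biomarkers(c("High", "Low/Moderate"), c(TRUE, FALSE))
#' @export
combine_biomarkers <- function(tmb_binary, pdl1_positive) {
  tb <- as.character(tmb_binary)
  if (!all(tb %in% c("High", "Low/Moderate"))) {
    abort("`tmb_binary` must be High or Low/Moderate")
  }
  if (!is.logical(pdl1_positive) || any(is.na(pdl1_positive))) {
    abort("`pdl1_positive` must be TRUE/FALSE")
  }
  if (length(tb) != length(pdl1_positive)) abort("length mismatch")
  cls <- case_when(
    tb == "Low/Moderate" & !pdl1_positive ~ "LM_neg",
    tb == "Low/Moderate" & pdl1_positive ~ "LM_pos",
    tb == "High" & pdl1_positive ~ "H_pos",
    .default = "H_neg"
  )
  factor(cls, levels = c("LM_neg", "LM_pos", "H_pos", "H_neg"))
}

#' Assign combined biomarker strata to a scored cohort table
#'
#' @param data tibble with `tmb_class` (Low/Moderate/High) and
#'   `tc_positive` columns.
#' @return the input with appended `tmb_binary` and `combined_class`.
#' @export
assign_strata <- function(data) {
  check_cols(data, c("tmb_class", "tc_positive"), "`data`")
  mutate(data,
    tmb_binary = dichotomize_tmb(.data$tmb_class),
    combined_class = combine_biomarkers(.data$tmb_binary, .data$tc_positive)
  )
}

#' Overlap of PD-L1-positive and TMB-high patients
#'
#' Venn-style summary of the two dichotomized biomarkers within a
#' subgroup: counts of patients positive for both, PD-L1 only, TMB-high
#' only, and neither. The four cells are mutually exclusive and sum to
#' the subgroup size. Because the published overlap percentages are
#' ambiguous about their denominator, percentages are reported under both
#' normalizations: the subgroup itself (`pct_subgroup`) and, when
#' `total_n` is given, the full cohort (`pct_total`).
#'
#' @param data tibble of stratified patients (see [assign_strata()]),
#'   already filtered to the subgroup of interest; non-empty.
#' @param total_n optional full-cohort size for the second normalization.
#' @return tibble with `category`, `count`, `pct_subgroup`, `pct_total`.
#' @export
overlap_summary <- function(data, total_n = NULL) {
  check_cols(data, "combined_class", "`data`")
  if (nrow(data) == 0) abort("empty subgroup: overlap undefined")
  cls <- factor(data$combined_class, levels = c("LM_neg", "LM_pos", "H_pos", "H_neg"))
  counts <- c(
    both = sum(cls == "H_pos"),
    pdl1_only = sum(cls == "LM_pos"),
    tmb_only = sum(cls == "H_neg"),
    neither = sum(cls == "LM_neg")
  )
  out <- tibble(
    category = names(counts),
    count = as.integer(counts),
    pct_subgroup = unname(round_half_up(100 * counts / nrow(data)))
  )
  if (!is.null(total_n)) {
    out$pct_total <- unname(round_half_up(100 * counts / total_n))
  }
  out
}
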