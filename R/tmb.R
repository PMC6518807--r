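#' Per-patient tumor mutational burden
#'
#' TMB is the number of retained somatic coding mutations (base
#' substitutions and indels; synonymous included under the default filter
#' configuration) divided by the size of the panel's coding territory in
#' megabases. Patients listed in `patients` but absent from the retained
#' set receive a count of 0.
#'
#' @param retained tibble of retained variants (e.g.
#'   `filter_cohort(...)$retained`) with a `patient_id` column; each row
#'   counts as one mutation event (multi-allelic sites contribute one row
#'   per alt allele).
#' @param panel a `tmb_panel` with positive territory.
#' @param patients optional character vector of all patient ids, so that
#'   zero-mutation patients appear with TMB 0.
#' @return tibble with `patient_id`, `mutation_count`, `territory_mb`,
#'   `tmb` (mutations/Mb).
#' @examples
#' panel <- generate_panel(1, 10, seed = 1)
#' compute_tmb(tibble::tibble(patient_id = rep("P1", 80)), panel)
#' @export
compute_tmb <- function(retained, panel, patients = NULL) {
  mb <- panel_territory_mb(panel)
  if (!is.numeric(mb) || mb <= 0) abort("panel territory must be positive")
  check_cols(retained, "patient_id", "`retained`")
  counts <- count(retained, .data$patient_id, name = "mutation_count")
  if (!is.null(patients)) {
    counts <- tibble(patient_id = patients) |>
      left_join(counts, by = "patient_id") |>
      mutate(mutation_count = if_else(is.na(.data$mutation_count),
                                      0L, as.integer(.data$mutation_count)))
  }
  counts |>
    mutate(territory_mb = mb, tmb = .data$mutation_count / mb) |>
    arrange(.data$patient_id)
}

#' Derive data-adaptive TMB cutoffs for the cohort
#'
#' The cohort is trichotomized with cutoffs derived from the pooled TMB
#' distribution (both histologies together): the high/moderate boundary
#' is `median + SD` and the moderate/low boundary is `median - SD/2`,
#' floored at 0 since TMB is non-negative. SD is the sample standard
#' deviation (n-1 denominator) by default.
#'
#' @param tmb numeric vector of per-patient TMB values (>= 2 values).
#' @param sd_method `"sample"` (n-1, default) or `"population"` (n).
#' @return A `tmb_cutoffs` list: `low_cutoff`, `high_cutoff`, `median`,
#'   `sd`, `method_tag`.
#' @examples
#' derive_cutoffs(c(2, 4, 8, 12, 14))
#' @export
derive_cutoffs <- function(tmb, sd_method = c("sample", "population")) {
  sd_method <- arg_match(sd_method)
  if (!is.numeric(tmb) || length(tmb) < 2 || any(!is.finite(tmb))) {
    abort("at least 2 finite TMB values are required (SD undefined otherwise)")
  }
  if (any(tmb < 0)) abort("TMB values must be non-negative")
  m <- median(tmb)
  s <- sd(tmb)
  if (sd_method == "population") s <- s * sqrt((length(tmb) - 1) / length(tmb))
  structure(
    list(
      low_cutoff = max(m - s / 2, 0),
      high_cutoff = m + s,
      median = m,
      sd = s,
      method_tag = paste0("median+sd/median-sd2_", sd_method)
    ),
    class = "tmb_cutoffs"
  )
}

#' @export
print.tmb_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<tmb_cutoffs> High >= %.3f, Low < %.3f (median %.3f, SD %.3f)\n",
    x$high_cutoff, x$low_cutoff, x$median, x$sd
  ))
  invisible(x)
}

#' @rdname derive_cutoffs
#' @param x a `tmb_cutoffs`.
#' @param ... unused.
#' @return `glance()` returns the cutoffs as a one-row tibble.
#' @method glance tmb_cutoffs
#' @export
glance.tmb_cutoffs <- function(x, ...) {
  tibble(low_cutoff = x$low_cutoff, high_cutoff = x$high_cutoff,
         median = x$median, sd = x$sd, method_tag = x$method_tag)
}

#' Classify TMB values into Low / Moderate / High
#'
#' Boundary inclusivity follows the standard presentation: High at
#' `tmb >= high_cutoff`, Low at `tmb < low_cutoff`, Moderate in between
#' (`low_cutoff <= tmb < high_cutoff`).
#'
#' @param tmb numeric vector of TMB values.
#' @param cutoffs a `tmb_cutoffs` from [derive_cutoffs()].
#' @return factor with levels Low, Moderate, High.
#' @examples
#' cuts <- derive_cutoffs(c(2, 4, 8, 12, 14))
#' classify_tmb(c(1, 6, 14), cuts)
#' @export
classify_tmb <- function(tmb, cutoffs) {
  stopifnot(inherits(cutoffs, "tmb_cutoffs"))
  if (cutoffs$low_cutoff > cutoffs$high_cutoff) {
    abort("invalid cutoffs: low_cutoff > high_cutoff")
  }
  cls <- case_when(
    tmb >= cutoffs$high_cutoff ~ "High",
    tmb < cutoffs$low_cutoff ~ "Low",
    .default = "Moderate"
  )
  factor(cls, levels = c("Low", "Moderate", "High"))
}

#' Collapse the three TMB classes to the two-group stratification
#'
#' @param tmb_class factor/character of Low/Moderate/High classes.
#' @return factor with levels `Low/Moderate`, `High`.
#' @export
dichotomize_tmb <- function(tmb_class) {
  cls <- as.character(tmb_class)
  if (!all(cls %in% c("Low", "Moderate", "High"))) {
    abort("`tmb_class` must be Low, Moderate or High")
  }
  factor(if_else(cls == "High", "High", "Low/Moderate"),
         levels = c("Low/Moderate", "High"))
}

#' Write per-patient TMB results and cutoffs
#'
#' @param tmb_table tibble from [compute_tmb()] with a `tmb_class` column
#'   (add one via [classify_tmb()]).
#' @param cutoffs a `tmb_cutoffs`.
#' @param tsv_path,json_path output paths (TSV table; cutoffs JSON).
#' @return `tsv_path`, invisibly. Territory is reported to 0.1 Mb; all
#'   internal arithmetic stays unrounded.
#' @export
write_tmb_results <- function(tmb_table, cutoffs, tsv_path, json_path) {
  check_cols(tmb_table, c("patient_id", "mutation_count", "territory_mb", "tmb"),
             "`tmb_table`")
  out <- mutate(tmb_table, territory_mb = round(.data$territory_mb, 1))
  readr::write_tsv(out, tsv_path)
  jsonlite::write_json(unclass(cutoffs), json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
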