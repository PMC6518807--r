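#' PD-L1 tumor-cell (TC) category from staining percentage
#'
#' Semiquantitative ladder over the percentage of PD-L1-expressing tumor
#' cells: TC3 at >= 50%, TC2 at 5 to < 50%, TC1 at >= 1 to < 5%, TC0 at
#' < 1%. Bins are half-open with inclusive lower bounds.
#'
#' @param tc_pct percentage(s) in `[0, 100]`.
#' @return factor with levels TC0-TC3.
#' @examples
#' tc_category(c(0.99, 1, 5, 50))
#' @export
tc_category <- function(tc_pct) {
  check_pct(tc_pct, "tc_pct")
  cut(tc_pct, breaks = c(0, 1, 5, 50, 100),
      labels = c("TC0", "TC1", "TC2", "TC3"),
      right = FALSE, include.lowest = TRUE)
}

#' PD-L1 immune-cell (IC) category from staining percentage
#'
#' Ladder over the percentage of the tumor area occupied by PD-L1
#' positive immune cells: IC3 at >= 10%, IC2 at >= 5 to < 10%, IC1 at
#' >= 1 to < 5%, IC0 at < 1%.
#'
#' @param ic_pct percentage(s) in `[0, 100]`.
#' @return factor with levels IC0-IC3.
#' @examples
#' ic_category(c(0, 1, 5, 10))
#' @export
ic_category <- function(ic_pct) {
  check_pct(ic_pct, "ic_pct")
  cut(ic_pct, breaks = c(0, 1, 5, 10, 100),
      labels = c("IC0", "IC1", "IC2", "IC3"),
      right = FALSE, include.lowest = TRUE)
}

check_pct <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 100)) {
    abort(sprintf("`%s` must be percentages in [0, 100]", name))
  }
  invisible(x)
}

pdl1_grades <- c("negative", "weak", "moderate", "strong")

#' Score PD-L1 readouts for a cohort
#'
#' Converts raw TC/IC staining percentages into the categorical ladders,
#' semiquantitative grades (category 0 -> negative, 1 -> weak positive,
#' 2 -> moderate positive, 3 -> strong positive) and any-positive calls
#' per compartment. TC and IC are scored independently; an optional
#' combined grade (the stronger of the two compartments) is off by
#' default, since survival analyses here use TC expression only.
#'
#' @param data data frame with columns `tc_pct` and `ic_pct` (e.g. the
#'   clinical table).
#' @param combined also add a `combined_grade` column (default `FALSE`).
#' @return the input with appended `tc_category`, `ic_category`,
#'   `tc_grade`, `ic_grade`, `tc_positive`, `ic_positive` columns.
#' @examples
#' score_pdl1(tibble::tibble(tc_pct = c(60, 0, 4.9), ic_pct = c(0.5, 0, 9.9)))
#' @export
score_pdl1 <- function(data, combined = FALSE) {
  check_cols(data, c("tc_pct", "ic_pct"), "`data`")
  out <- mutate(data,
    tc_category = tc_category(.data$tc_pct),
    ic_category = ic_category(.data$ic_pct),
    tc_grade = factor(pdl1_grades[as.integer(.data$tc_category)],
                      levels = pdl1_grades),
    ic_grade = factor(pdl1_grades[as.integer(.data$ic_category)],
                      levels = pdl1_grades),
    tc_positive = .data$tc_category != "TC0",
    ic_positive = .data$ic_category != "IC0"
  )
  if (isTRUE(combined)) {
    out <- mutate(out, combined_grade = factor(
      pdl1_grades[pmax(as.integer(.data$tc_category),
                       as.integer(.data$ic_category))],
      levels = pdl1_grades
    ))
  }
  out
}

#' Cohort frequency table of PD-L1 intensity
#'
#' Percent frequencies of PD-L1 intensity per compartment, either in four
#' categories (negative, weak, moderate, strong positive) or collapsed to
#' two (negative, positive). Percentages are rounded half-up to integer
#' percent, the convention that reproduces published clinical frequency
#' tables; raw counts and exact proportions are returned alongside.
#'
#' @param scores a scored cohort from [score_pdl1()] (non-empty).
#' @param compartment `"tc"` or `"ic"`.
#' @param n_categories 4 (default) or 2.
#' @return tibble with `category`, `count`, `proportion`, `pct`.
#' @examples
#' cohort <- tibble::tibble(tc_pct = c(0, 0, 30, 80), ic_pct = c(0, 2, 0, 12))
#' pdl1_frequency_table(score_pdl1(cohort), "tc", 2)
#' @export
pdl1_frequency_table <- function(scores, compartment = c("tc", "ic"),
                                 n_categories = 4) {
  compartment <- arg_match(compartment)
  if (!n_categories %in% c(2, 4)) abort("`n_categories` must be 2 or 4")
  col <- paste0(compartment, "_grade")
  check_cols(scores, col, "`scores`")
  if (nrow(scores) == 0) abort("empty cohort: frequencies undefined")
  g <- scores[[col]]
  if (n_categories == 2) {
    g <- factor(if_else(g == "negative", "negative", "positive"),
                levels = c("negative", "positive"))
  }
  tab <- table(g)
  tibble(
    category = names(tab),
    count = as.integer(tab),
    proportion = as.numeric(tab) / nrow(scores),
    pct = round_half_up(100 * as.numeric(tab) / nrow(scores))
  )
}
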