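#' Bar chart of PD-L1 intensity frequencies
#'
#' @param freq a frequency tibble from [pdl1_frequency_table()], or a
#'   row-bound stack of several with `histology`/`table` columns for
#'   faceting.
#' @return a ggplot object.
#' @export
plot_pdl1_frequencies <- function(freq) {
  check_cols(freq, c("category", "pct"), "`freq`")
  p <- ggplot2::ggplot(freq, ggplot2::aes(.data$category, .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "Percent of cohort") +
    ggplot2::theme_minimal()
  if (all(c("histology", "table") %in% names(freq))) {
    p <- p + ggplot2::facet_grid(histology ~ table, scales = "free_x")
  }
  p
}

#' TMB distribution with class cutoffs
#'
#' Per-patient TMB values on a log-friendly scale with the derived
#' high/moderate and moderate/low cutoffs overlaid.
#'
#' @param tmb_table tibble from [compute_tmb()].
#' @param cutoffs a `tmb_cutoffs`.
#' @return a ggplot object.
#' @export
plot_tmb_distribution <- function(tmb_table, cutoffs) {
  check_cols(tmb_table, "tmb", "`tmb_table`")
  ggplot2::ggplot(tmb_table, ggplot2::aes(.data$tmb)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", color = "white") +
    ggplot2::geom_vline(xintercept = c(cutoffs$low_cutoff, cutoffs$high_cutoff),
                        linetype = "dashed", color = c("orange", "red")) +
    ggplot2::labs(x = "TMB (mutations/Mb)", y = "Patients") +
    ggplot2::theme_minimal()
}
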