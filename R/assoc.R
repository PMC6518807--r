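#' Association test for a contingency table
#'
#' Pearson's chi-squared test, switching to Fisher's exact test whenever
#' any expected cell count falls below 5 (the conventional rule; the
#' exact test enumerates r x c tables via the network algorithm for small
#' tables). The 2x2 chi-square is computed without continuity correction
#' by default; both variants are exposed. The method actually used is
#' recorded in the result.
#'
#' @param tab a matrix/table of non-negative integer counts, or a data
#'   frame with two categorical columns to cross-tabulate.
#' @param method `"auto"` (default rule), `"chisq"` or `"fisher"`.
#' @param correct apply Yates continuity correction to 2x2 chi-square
#'   (default `FALSE`).
#' @return one-row tibble: `p_value`, `statistic` (`NA` for Fisher),
#'   `method_used`.
#' @examples
#' contingency_test(matrix(c(45, 41, 41, 9), 2, byrow = TRUE))
#' @export
contingency_test <- function(tab, method = c("auto", "chisq", "fisher"),
                             correct = FALSE) {
  method <- arg_match(method)
  if (is.data.frame(tab)) {
    if (ncol(tab) != 2) abort("data-frame input must have exactly 2 columns")
    tab <- table(tab[[1]], tab[[2]])
  }
  tab <- as.matrix(tab)
  check_counts(as.vector(tab), "tab")
  if (sum(tab) == 0) abort("all-zero table: association undefined")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: zero row or column margin")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2x2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- switch(method,
    auto = if (any(expected < 5)) "fisher" else "chisq",
    method
  )
  if (use == "fisher") {
    ft <- fisher.test(tab)
    tibble(p_value = ft$p.value, statistic = NA_real_, method_used = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    tibble(p_value = ct$p.value, statistic = unname(ct$statistic),
           method_used = if (correct) "chisq_corrected" else "chisq")
  }
}

#' Spearman rank correlation with midrank ties
#'
#' Two-sided test of monotone association (used here for PD-L1 TC
#' percentage vs TMB). Ties are handled by midranks; the p-value uses the
#' t approximation with ties and the exact null distribution for small
#' untied samples, as in [stats::cor.test].
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis rank test across `k >= 2` groups,
#' followed by Dunn's z tests for all `k(k-1)/2` pairs on the pooled
#' midranks. Pairwise p-values are unadjusted by default (reported as
#' single comparisons); Bonferroni or any [stats::p.adjust] method is
#' available.
#'
#' @param data data frame with a numeric value column and a group column.
#' @param value,group column names (strings).
#' @param p_adjust multiplicity adjustment for the pairwise p-values
#'   (default `"none"`).
#' @return list with `kw` (one-row tibble: `statistic`, `df`, `p_value`)
#'   and `pairwise` (tibble: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(data, value = "value", group = "group",
                         p_adjust = "none") {
  check_cols(data, c(value, group), "`data`")
  v <- data[[value]]
  g <- droplevels(factor(data[[group]]))
  if (any(is.na(v))) abort("missing values in `value`")
  if (nlevels(g) < 2) abort("need >= 2 non-empty groups")
  if (any(table(g) == 0)) abort("empty group")
  kw <- kruskal.test(v, g)
  n <- length(v)
  r <- rank(v)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_rank[p[1]] - mean_rank[p[2]]) /
      sqrt(sigma2 * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  list(
    kw = tibble(
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p_value = kw$p.value
    ),
    pairwise = tibble(
      group1 = pairs[1, ],
      group2 = pairs[2, ],
      z = unname(z),
      p_value = unname(p_raw),
      p_adjusted = p.adjust(unname(p_raw), method = p_adjust)
    )
  )
}
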