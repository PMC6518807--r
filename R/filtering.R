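#' Somatic filter-chain configuration
#'
#' Thresholds of the paired tumor/normal somatic calling and exclusion
#' filters. Defaults follow the standard targeted-panel workflow this
#' package implements: minimum 8x coverage in the normal (peripheral
#' blood lymphocyte) sample and 6x in tumor tissue; a one-sided exact
#' test p-value threshold of 0.05 to call a site somatic (inclusive by
#' default); variants kept only when fewer than 90% of tumor alt reads
#' sit on one strand; population-database (ExAC-style) germline exclusion
#' at two or more observations; a PolyPhen-2-style benign cutoff of 0.452
#' applied to missense variants; synonymous variants counted toward TMB
#' (to reduce sampling noise) unless disabled.
#'
#' @param min_normal_depth minimum normal-sample depth (reads).
#' @param min_tumor_depth minimum tumor-sample depth (reads).
#' @param somatic_p_threshold p-value threshold for the paired exact test.
#' @param p_inclusive call somatic at `p <= threshold` (`TRUE`, default)
#'   or `p < threshold`.
#' @param alternative `"greater"` (one-sided, tumor alt-fraction exceeds
#'   normal; default) or `"two.sided"`.
#' @param strand_bias_max maximum tolerated majority-strand fraction
#'   (exclusive); variants with fraction `>= strand_bias_max` are dropped.
#' @param popdb_max_count maximum tolerated population-database
#'   observation count (default 1, i.e. exclude >= 2).
#' @param benign_score_threshold missense variants with deleteriousness
#'   score strictly below this are excluded as benign.
#' @param count_synonymous_for_tmb keep synonymous variants (default
#'   `TRUE`); `FALSE` restricts to nonsynonymous.
#' @param sd_method passed through to cutoff derivation downstream
#'   (`"sample"` or `"population"`).
#' @param strand_missing verdict for variants whose strand counts are
#'   unavailable: `"fail"` (default) or `"pass"`.
#' @return A validated `filter_config` list.
#' @export
filter_config <- function(min_normal_depth = 8,
                          min_tumor_depth = 6,
                          somatic_p_threshold = 0.05,
                          p_inclusive = TRUE,
                          alternative = c("greater", "two.sided"),
                          strand_bias_max = 0.90,
                          popdb_max_count = 1,
                          benign_score_threshold = 0.452,
                          count_synonymous_for_tmb = TRUE,
                          sd_method = c("sample", "population"),
                          strand_missing = c("fail", "pass")) {
  alternative <- arg_match(alternative)
  sd_method <- arg_match(sd_method)
  strand_missing <- arg_match(strand_missing)
  if (min_normal_depth <= 0 || min_tumor_depth <= 0) {
    abort("coverage thresholds must be positive")
  }
  check_prob(somatic_p_threshold, "somatic_p_threshold")
  if (!is.numeric(strand_bias_max) || strand_bias_max <= 0 || strand_bias_max > 1) {
    abort("`strand_bias_max` must be in (0, 1]")
  }
  check_counts(popdb_max_count, "popdb_max_count")
  check_prob(benign_score_threshold, "benign_score_threshold")
  structure(
    list(
      min_normal_depth = min_normal_depth,
      min_tumor_depth = min_tumor_depth,
      somatic_p_threshold = somatic_p_threshold,
      p_inclusive = isTRUE(p_inclusive),
      alternative = alternative,
      strand_bias_max = strand_bias_max,
      popdb_max_count = popdb_max_count,
      benign_score_threshold = benign_score_threshold,
      count_synonymous_for_tmb = isTRUE(count_synonymous_for_tmb),
      sd_method = sd_method,
      strand_missing = strand_missing
    ),
    class = "filter_config"
  )
}

# fixed evaluation order of the filter chain; the audit trail lists failed
# filters in this order
filter_reason_order <- c(
  "coverage_normal", "coverage_tumor", "not_somatic_p", "strand_bias",
  "noncoding", "popdb_germline", "dbsnp_germline", "zygosity_germline",
  "benign", "synonymous"
)

#' One-sided exact test for somatic status on paired allele counts
#'
#' The paired-caller test on the 2x2 table (tumor vs normal) x (ref vs
#' alt): under the null the tumor alt-allele fraction does not exceed the
#' normal's, and the p-value is the hypergeometric tail probability of
#' seeing at least the observed tumor alt count given the margins
#' (Fisher's exact test, one-sided). Vectorized over variants.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt read counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return p-value(s) in `[0,1]`.
#' @examples
#' somatic_p(10, 10, 20, 0)   # clearly somatic
#' somatic_p(10, 5, 10, 5)    # identical fractions: not somatic
#' @export
somatic_p <- function(tumor_ref, tumor_alt, normal_ref, normal_alt,
                      alternative = c("greater", "two.sided")) {
  alternative <- arg_match(alternative)
  check_counts(tumor_ref, "tumor_ref"); check_counts(tumor_alt, "tumor_alt")
  check_counts(normal_ref, "normal_ref"); check_counts(normal_alt, "normal_alt")
  tumor_depth <- tumor_ref + tumor_alt
  normal_depth <- normal_ref + normal_alt
  if (any(tumor_depth == 0) || any(normal_depth == 0)) {
    abort("uncallable site: zero read depth in tumor or normal sample")
  }
  m <- tumor_alt + normal_alt         # total alt
  nn <- tumor_ref + normal_ref        # total ref
  p_greater <- phyper(tumor_alt - 1, m, nn, tumor_depth, lower.tail = FALSE)
  if (alternative == "greater") {
    return(pmin(p_greater, 1))
  }
  # two-sided: sum of hypergeometric point masses <= observed mass
  mapply(function(ta, mm, nnn, k) {
    supp <- max(0, k - nnn):min(k, mm)
    d <- stats::dhyper(supp, mm, nnn, k)
    sum(d[d <= stats::dhyper(ta, mm, nnn, k) * (1 + 1e-7)])
  }, tumor_alt, m, nn, tumor_depth)
}

#' Majority-strand fraction of alt-supporting reads
#'
#' Strand bias is the imbalance of a variant's supporting reads between
#' forward and reverse sequencing strands, a sequencing-artifact
#' signature. The statistic is `max(fwd, rev) / (fwd + rev)`; a variant
#' is kept when the fraction is strictly below the configured maximum
#' (default 0.90).
#'
#' @param alt_fwd,alt_rev alt-supporting read counts per strand (tumor).
#' @return fraction(s) in `[0.5, 1]`.
#' @examples
#' strand_bias_fraction(5, 5)    # 0.5, balanced
#' strand_bias_fraction(9, 1)    # 0.9, dropped at the default threshold
#' @export
strand_bias_fraction <- function(alt_fwd, alt_rev) {
  check_counts(alt_fwd, "alt_fwd"); check_counts(alt_rev, "alt_rev")
  tot <- alt_fwd + alt_rev
  if (any(tot == 0)) {
    abort("no alt-supporting reads: strand bias undefined")
  }
  pmax(alt_fwd, alt_rev) / tot
}

#' Apply the full somatic filter chain to candidate variants
#'
#' Evaluates every filter for every variant (no short-circuiting), so the
#' audit trail lists all failed filters in fixed chain order: normal
#' coverage, tumor coverage, paired somatic exact test, strand bias,
#' coding/panel membership, population-database germline exclusion,
#' known-germline (dbSNP-style) flag, zygosity-algorithm germline call,
#' benign missense score (and, when synonymous counting is disabled,
#' synonymous exclusion). A variant is kept iff its reason list is empty.
#'
#' @param variants tibble of variant records (see [generate_variants()]
#'   for the schema); `deleterious_score` may be `NA` for non-missense
#'   classes, where the benign filter passes vacuously.
#' @param config a [filter_config()].
#' @param panel a `tmb_panel`; variants outside the panel territory (or on
#'   contigs absent from it) fail the coding/panel-membership filter.
#' @return The input tibble with appended columns `somatic_p_value`,
#'   `strand_fraction`, `kept` and `reasons` (comma-joined failed-filter
#'   tags, `""` when kept).
#' @export
apply_filters <- function(variants, config = filter_config(), panel) {
  check_cols(variants, c(
    "chrom", "pos", "ref", "alt", "tumor_ref", "tumor_alt",
    "normal_ref", "normal_alt", "alt_fwd", "alt_rev", "consequence",
    "popdb_count", "known_germline", "zygosity_call", "deleterious_score"
  ), "`variants`")
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(variants)
  if (n == 0) {
    return(mutate(variants, somatic_p_value = numeric(0),
                  strand_fraction = numeric(0), kept = logical(0),
                  reasons = character(0)))
  }
  v <- variants
  tumor_depth <- v$tumor_ref + v$tumor_alt
  normal_depth <- v$normal_ref + v$normal_alt

  fail <- matrix(FALSE, n, length(filter_reason_order),
                 dimnames = list(NULL, filter_reason_order))
  fail[, "coverage_normal"] <- normal_depth < config$min_normal_depth
  fail[, "coverage_tumor"] <- tumor_depth < config$min_tumor_depth

  p <- rep(NA_real_, n)
  callable <- tumor_depth > 0 & normal_depth > 0
  if (any(callable)) {
    p[callable] <- somatic_p(
      v$tumor_ref[callable], v$tumor_alt[callable],
      v$normal_ref[callable], v$normal_alt[callable],
      alternative = config$alternative
    )
  }
  somatic_call <- if (config$p_inclusive) {
    p <= config$somatic_p_threshold
  } else {
    p < config$somatic_p_threshold
  }
  fail[, "not_somatic_p"] <- !callable | is.na(somatic_call) | !somatic_call

  sf <- rep(NA_real_, n)
  has_strand <- !is.na(v$alt_fwd) & !is.na(v$alt_rev) & (v$alt_fwd + v$alt_rev) > 0
  if (any(has_strand)) {
    sf[has_strand] <- strand_bias_fraction(v$alt_fwd[has_strand], v$alt_rev[has_strand])
  }
  fail[, "strand_bias"] <- if_else(
    has_strand, sf >= config$strand_bias_max,
    config$strand_missing == "fail", missing = config$strand_missing == "fail"
  )

  fail[, "noncoding"] <- v$consequence == "noncoding" |
    !panel_contains(panel, v$chrom, v$pos)
  fail[, "popdb_germline"] <- !is.na(v$popdb_count) &
    v$popdb_count > config$popdb_max_count
  fail[, "dbsnp_germline"] <- v$known_germline %in% TRUE
  fail[, "zygosity_germline"] <- v$zygosity_call %in% "germline"
  fail[, "benign"] <- v$consequence == "missense" &
    !is.na(v$deleterious_score) &
    v$deleterious_score < config$benign_score_threshold
  if (!config$count_synonymous_for_tmb) {
    fail[, "synonymous"] <- v$consequence == "synonymous"
  }

  reasons <- apply(fail, 1, function(row) {
    paste(filter_reason_order[row], collapse = ",")
  })
  mutate(v,
    somatic_p_value = p,
    strand_fraction = sf,
    kept = reasons == "",
    reasons = reasons
  )
}

#' Filter a whole cohort and keep a per-variant audit trail
#'
#' Runs [apply_filters()] per patient and returns both the retained
#' variant set and the complete audit log (one row per candidate with
#' verdict, failed-filter reasons, somatic p-value and strand fraction).
#' Candidate counts are conserved: every input row appears in the audit
#' log exactly once.
#'
#' @param variants tibble of candidate variants across patients
#'   (`patient_id` column required).
#' @param config a [filter_config()].
#' @param panel a `tmb_panel`.
#' @return A `cohort_filter` list with elements `retained` (kept
#'   variants), `audit` (all candidates with verdicts) and `summary`
#'   (per-patient kept/dropped counts).
#' @export
filter_cohort <- function(variants, config = filter_config(), panel) {
  check_cols(variants, "patient_id", "`variants`")
  dup <- variants |>
    count(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    filter(n > 1)
  if (nrow(variants) > 0 && nrow(dup) > 0) {
    abort(sprintf(
      "duplicate variant key within patient %s at %s:%d %s>%s",
      dup$patient_id[1], dup$chrom[1], dup$pos[1], dup$ref[1], dup$alt[1]
    ))
  }
  audit <- apply_filters(variants, config, panel)
  stopifnot(nrow(audit) == nrow(variants))
  summary <- audit |>
    group_by(.data$patient_id) |>
    summarise(n_candidates = n(), n_kept = sum(.data$kept),
              n_dropped = sum(!.data$kept), .groups = "drop")
  structure(
    list(retained = filter(audit, .data$kept),
         audit = audit, summary = summary, config = config),
    class = "cohort_filter"
  )
}

#' @export
print.cohort_filter <- function(x, ...) {
  cat("<cohort_filter>\n")
  cat(sprintf("  %d candidates, %d retained (%.1f%%), %d patients\n",
              nrow(x$audit), nrow(x$retained),
              if (nrow(x$audit) > 0) 100 * nrow(x$retained) / nrow(x$audit) else 0,
              nrow(x$summary)))
  invisible(x)
}

#' @rdname filter_cohort
#' @param x a `cohort_filter`.
#' @param ... unused.
#' @return `tidy()` returns the audit log as a tibble.
#' @method tidy cohort_filter
#' @export
tidy.cohort_filter <- function(x, ...) as_tibble(x$audit)

#' Write the filter audit log as TSV
#'
#' @param x a `cohort_filter`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(x, path) {
  stopifnot(inherits(x, "cohort_filter"))
  cols <- c("patient_id", "chrom", "pos", "ref", "alt", "kept", "reasons",
            "somatic_p_value", "strand_fraction")
  readr::write_tsv(select(x$audit, dplyr::all_of(cols)), path)
  invisible(path)
}
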