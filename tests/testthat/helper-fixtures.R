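# In-code fixtures shared across tests.

# single 1-Mb interval panel: positions 1..1e6 are inside
toy_panel <- function(mb = 1) {
  panel_definition(tibble::tibble(chrom = "chr1", start = 0, end = mb * 1e6))
}

# a variant that passes every default filter; override fields as needed
toy_variant <- function(...) {
  v <- tibble::tibble(
    patient_id = "P1", chrom = "chr1", pos = 100L, ref = "A", alt = "T",
    tumor_ref = 60L, tumor_alt = 40L, normal_ref = 100L, normal_alt = 0L,
    alt_fwd = 22L, alt_rev = 18L,
    consequence = "missense", popdb_count = 0L, known_germline = FALSE,
    zygosity_call = "somatic", deleterious_score = 0.9,
    truth_somatic = TRUE
  )
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# independent brute-force re-evaluation of the filter rules, written as
# plain per-variant logic (no vectorization, no shared helpers)
brute_force_verdict <- function(v, cfg, panel_start, panel_end,
                                panel_chrom = "chr1") {
  reasons <- character(0)
  nd <- v$normal_ref + v$normal_alt
  td <- v$tumor_ref + v$tumor_alt
  if (nd < cfg$min_normal_depth) reasons <- c(reasons, "coverage_normal")
  if (td < cfg$min_tumor_depth) reasons <- c(reasons, "coverage_tumor")
  p <- if (td == 0 || nd == 0) NA_real_ else {
    # hypergeometric tail by explicit enumeration
    m <- v$tumor_alt + v$normal_alt
    n_ref <- v$tumor_ref + v$normal_ref
    ks <- v$tumor_alt:min(td, m)
    sum(choose(m, ks) * choose(n_ref, td - ks)) / choose(m + n_ref, td)
  }
  somatic <- !is.na(p) && if (cfg$p_inclusive) p <= cfg$somatic_p_threshold else
    p < cfg$somatic_p_threshold
  if (!somatic) reasons <- c(reasons, "not_somatic_p")
  tot <- v$alt_fwd + v$alt_rev
  if (is.na(tot) || tot == 0) {
    if (cfg$strand_missing == "fail") reasons <- c(reasons, "strand_bias")
  } else if (max(v$alt_fwd, v$alt_rev) / tot >= cfg$strand_bias_max) {
    reasons <- c(reasons, "strand_bias")
  }
  inside <- v$chrom == panel_chrom && v$pos >= panel_start + 1 &&
    v$pos <= panel_end
  if (v$consequence == "noncoding" || !inside) reasons <- c(reasons, "noncoding")
  if (v$popdb_count > cfg$popdb_max_count) reasons <- c(reasons, "popdb_germline")
  if (isTRUE(v$known_germline)) reasons <- c(reasons, "dbsnp_germline")
  if (v$zygosity_call == "germline") reasons <- c(reasons, "zygosity_germline")
  if (v$consequence == "missense" && !is.na(v$deleterious_score) &&
      v$deleterious_score < cfg$benign_score_threshold) {
    reasons <- c(reasons, "benign")
  }
  if (!cfg$count_synonymous_for_tmb && v$consequence == "synonymous") {
    reasons <- c(reasons, "synonymous")
  }
  list(kept = length(reasons) == 0, reasons = reasons)
}

# random variant drawer for oracle-equivalence checks (spans all filter
# boundaries, including degenerate strand counts)
random_variant <- function(patient = "P1", pos = NULL) {
  ta <- sample(0:30, 1)
  fwd <- if (ta > 0) sample(0:ta, 1) else 0L
  toy_variant(
    patient_id = patient,
    pos = if (is.null(pos)) sample(c(50L, 5e5L, 2e6L), 1) else pos,
    tumor_ref = sample(0:40, 1), tumor_alt = ta,
    normal_ref = sample(0:30, 1), normal_alt = sample(0:6, 1),
    alt_fwd = as.integer(fwd), alt_rev = as.integer(ta - fwd),
    consequence = sample(c("missense", "synonymous", "nonsense",
                           "frameshift_indel", "inframe_indel", "noncoding"), 1),
    popdb_count = sample(0:4, 1),
    known_germline = runif(1) < 0.3,
    zygosity_call = sample(c("somatic", "germline", "ambiguous"), 1),
    deleterious_score = if (runif(1) < 0.2) NA_real_ else round(runif(1), 3)
  )
}
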