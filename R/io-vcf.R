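#' Write per-patient candidate variants as VCF v4.2
#'
#' Serializes one patient's paired count evidence: FORMAT fields `DP`
#' (depth), `AD` (ref,alt read counts), `ADF`/`ADR` (alt-supporting
#' forward/reverse counts, tumor only) for the `TUMOR` and `NORMAL`
#' sample columns, and annotation INFO keys `CSQ` (consequence class),
#' `PDBC` (population-database observation count), `KGL` (known-germline
#' flag), `SGZ` (somatic-germline zygosity call) and `DSC`
#' (deleteriousness score). A simulated truth label, when present, is
#' carried in `TRUTH`.
#'
#' @param variants one patient's variant tibble (see
#'   [generate_variants()]).
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  check_cols(variants, c(
    "chrom", "pos", "ref", "alt", "tumor_ref", "tumor_alt", "normal_ref",
    "normal_alt", "alt_fwd", "alt_rev", "consequence", "popdb_count",
    "known_germline", "zygosity_call", "deleterious_score"
  ), "`variants`")
  has_truth <- "truth_somatic" %in% names(variants)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=tmbpdl1",
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=PDBC,Number=1,Type=Integer,Description="Population database observation count">',
    '##INFO=<ID=KGL,Number=0,Type=Flag,Description="Known germline (dbSNP-style)">',
    '##INFO=<ID=SGZ,Number=1,Type=String,Description="Somatic-germline zygosity call">',
    '##INFO=<ID=DSC,Number=1,Type=Float,Description="Deleteriousness score in [0,1]">',
    if (has_truth) '##INFO=<ID=TRUTH,Number=1,Type=String,Description="Simulated ground-truth label">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read counts">',
    '##FORMAT=<ID=ADF,Number=1,Type=Integer,Description="Alt-supporting reads, forward strand">',
    '##FORMAT=<ID=ADR,Number=1,Type=Integer,Description="Alt-supporting reads, reverse strand">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "TUMOR", "NORMAL"), collapse = "\t")
  )
  info <- sprintf(
    "CSQ=%s;PDBC=%d%s;SGZ=%s%s%s",
    variants$consequence,
    variants$popdb_count,
    if_else(variants$known_germline, ";KGL", ""),
    variants$zygosity_call,
    if_else(is.na(variants$deleterious_score), "",
            sprintf(";DSC=%.4f", variants$deleterious_score)),
    if (has_truth) {
      if_else(variants$truth_somatic, ";TRUTH=somatic", ";TRUTH=germline")
    } else ""
  )
  tumor <- sprintf("%d:%d,%d:%d:%d",
                   variants$tumor_ref + variants$tumor_alt,
                   variants$tumor_ref, variants$tumor_alt,
                   variants$alt_fwd, variants$alt_rev)
  normal <- sprintf("%d:%d,%d:.:.",
                    variants$normal_ref + variants$normal_alt,
                    variants$normal_ref, variants$normal_alt)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD:ADF:ADR\t%s\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  info, tumor, normal)
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read candidate variants from a VCF
#'
#' Parses a VCF v4.2 (via vcfR) with the sample and key conventions of
#' [write_variants_vcf()]. Multi-allelic sites are split into one record
#' per alt allele (each allele is a distinct mutation event); for split
#' records the per-strand alt counts are unavailable and set to `NA`.
#' Missing optional annotations default to permissive values (consequence
#' `missense`, population count 0, not known-germline, zygosity
#' `ambiguous`, score `NA`) with a warning.
#'
#' @param path VCF path.
#' @param patient_id id recorded on every returned row (default: file
#'   name without extension).
#' @param tumor_sample,normal_sample sample column names.
#' @return variant tibble in the package schema.
#' @export
read_variants <- function(path, patient_id = NULL,
                          tumor_sample = "TUMOR", normal_sample = "NORMAL") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required to read VCF files")
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  for (s in c(tumor_sample, normal_sample)) {
    if (!s %in% colnames(gt)) {
      abort(sprintf("sample column `%s` not found in %s", s, path))
    }
  }
  if (nrow(fix) == 0) return(empty_variant_tbl())

  info <- fix[, "INFO"]
  info_field <- function(key, default = NA_character_) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    if (all(is.na(m)) && !all(grepl(paste0("(^|;)", key, "="), info))) {
      # key absent everywhere -> default silently handled by caller
    }
    if_else(is.na(m), default, m)
  }
  csq <- info_field("CSQ")
  pdbc <- suppressWarnings(as.integer(info_field("PDBC")))
  sgz <- info_field("SGZ")
  dsc <- suppressWarnings(as.numeric(info_field("DSC")))
  kgl <- grepl("(^|;)KGL(;|$)", info)
  truth <- info_field("TRUTH")

  missing_ann <- c(
    if (anyNA(csq)) "CSQ", if (anyNA(pdbc)) "PDBC", if (anyNA(sgz)) "SGZ"
  )
  if (length(missing_ann) > 0) {
    warn(sprintf(
      "missing annotation field(s) %s in %s: using permissive defaults",
      paste(missing_ann, collapse = ", "), basename(path)
    ))
  }
  csq[is.na(csq)] <- "missense"
  pdbc[is.na(pdbc)] <- 0L
  sgz[is.na(sgz)] <- "ambiguous"

  parse_sample <- function(col) {
    fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
    val <- strsplit(gt[, col], ":", fixed = TRUE)
    get <- function(key) {
      mapply(function(f, v) {
        i <- match(key, f)
        if (is.na(i) || i > length(v)) NA_character_ else v[i]
      }, fmt, val, USE.NAMES = FALSE)
    }
    list(ad = get("AD"), adf = get("ADF"), adr = get("ADR"))
  }
  tum <- parse_sample(tumor_sample)
  nor <- parse_sample(normal_sample)
  if (all(is.na(tum$ad)) || all(is.na(nor$ad))) {
    abort("FORMAT field AD (ref,alt counts) is required in tumor and normal")
  }

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rows <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))

  ad_num <- function(ad_str, allele_index) {
    parts <- strsplit(ad_str, ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
    alt <- suppressWarnings(as.integer(mapply(
      function(p, j) if (length(p) > j) p[j + 1] else NA_character_,
      parts, allele_index
    )))
    list(ref = ref, alt = alt)
  }
  tum_ad <- ad_num(tum$ad[rows], alt_idx)
  nor_ad <- ad_num(nor$ad[rows], alt_idx)
  multi <- n_alt[rows] > 1
  adf <- suppressWarnings(as.integer(tum$adf[rows]))
  adr <- suppressWarnings(as.integer(tum$adr[rows]))
  adf[multi] <- NA_integer_
  adr[multi] <- NA_integer_
  if (any(is.na(adf) | is.na(adr))) {
    warn(sprintf(
      "strand counts unavailable for %d record(s) in %s: flagged unassessable for strand bias",
      sum(is.na(adf) | is.na(adr)), basename(path)
    ))
  }

  tibble(
    patient_id = patient_id,
    chrom = fix[rows, "CHROM"],
    pos = as.integer(fix[rows, "POS"]),
    ref = fix[rows, "REF"],
    alt = unname(unlist(alts)),
    tumor_ref = tum_ad$ref,
    tumor_alt = tum_ad$alt,
    normal_ref = nor_ad$ref,
    normal_alt = nor_ad$alt,
    alt_fwd = adf,
    alt_rev = adr,
    consequence = csq[rows],
    popdb_count = pdbc[rows],
    known_germline = kgl[rows],
    zygosity_call = sgz[rows],
    deleterious_score = dsc[rows],
    truth_somatic = if (all(is.na(truth))) NA else truth[rows] == "somatic"
  )
}
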