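#' Simulate paired tumor/normal candidate variants for one patient
#'
#' Emulates the count-level evidence consumed by the somatic filter chain:
#' every candidate carries tumor and normal ref/alt read counts, tumor
#' strand counts for the alt allele, a consequence class, a population
#' database observation count (ExAC-style), a known-germline flag
#' (dbSNP-style), a somatic/germline zygosity-algorithm call, and a
#' deleteriousness score in `[0,1]` (PolyPhen-2-style, defined for missense
#' only). Ground truth is carried in the `truth_somatic` column.
#'
#' Truly somatic coding variants arrive at rate `true_tmb` per Mb
#' (Poisson); an extra 15% somatic load is non-coding. Germline candidates
#' arrive at rate `somatic_rate * (1 - f) / f` for somatic fraction
#' `f in (0, 1)`; at the boundary `f = 0` the same candidate load is drawn
#' but labeled entirely germline, and at `f = 1` no germline candidates
#' are emitted. Germline variants get allele fractions matched between
#' tumor and normal and population-database counts >= 2 except for a
#' configured leakage fraction; somatic variants have normal allele
#' fraction near 0.
#'
#' @param panel a `tmb_panel`.
#' @param config a [cohort_config()].
#' @param patient_id patient identifier.
#' @param true_tmb true somatic coding mutation rate per Mb; drawn from
#'   the config's log-normal when `NULL`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [generate_cohort()]).
#' @return tibble of variant records; `attr(, "true_tmb")` holds the
#'   realized true TMB (somatic coding count / territory).
#' @export
generate_variants <- function(panel, config, patient_id,
                              true_tmb = NULL, seed = NULL) {
  if (!inherits(panel, "tmb_panel") || nrow(panel) == 0) {
    abort("`panel` must be a non-empty tmb_panel")
  }
  run <- function() {
    mb <- panel_territory_mb(panel)
    if (is.null(true_tmb)) {
      true_tmb <- rlnorm(1, config$tmb_meanlog, config$tmb_sdlog)
    }
    f <- config$somatic_fraction
    lambda_som_coding <- true_tmb * mb
    lambda_som_nc <- 0.15 * true_tmb * mb
    lambda_som <- lambda_som_coding + lambda_som_nc
    if (f == 0) {
      n_som_coding <- 0L; n_som_nc <- 0L
      lambda_germ <- lambda_som
    } else {
      n_som_coding <- rpois(1, lambda_som_coding)
      n_som_nc <- rpois(1, lambda_som_nc)
      lambda_germ <- if (f == 1) 0 else lambda_som * (1 - f) / f
    }
    n_germ <- rpois(1, lambda_germ)
    n <- n_som_coding + n_som_nc + n_germ
    if (n == 0) {
      out <- empty_variant_tbl(patient_id)
      attr(out, "true_tmb") <- 0
      return(out)
    }

    somatic <- rep(c(TRUE, TRUE, FALSE), c(n_som_coding, n_som_nc, n_germ))
    consequence <- character(n)
    som_cod <- which(somatic)[seq_len(n_som_coding)]
    consequence[som_cod] <- sample(
      c("missense", "synonymous", "nonsense", "frameshift_indel", "inframe_indel"),
      n_som_coding, replace = TRUE, prob = c(0.55, 0.28, 0.06, 0.07, 0.04)
    )
    if (n_som_nc > 0) consequence[which(somatic)[n_som_coding + seq_len(n_som_nc)]] <- "noncoding"
    germ_idx <- which(!somatic)
    consequence[germ_idx] <- sample(
      c("missense", "synonymous", "noncoding", "inframe_indel"),
      n_germ, replace = TRUE, prob = c(0.45, 0.35, 0.15, 0.05)
    )

    # positions: interval weighted by length, uniform inside (1-based)
    len <- panel$end - panel$start
    iv <- sample.int(nrow(panel), n, replace = TRUE, prob = len)
    pos <- panel$start[iv] + 1 + floor(runif(n) * len[iv])
    alleles <- draw_alleles(consequence)

    # allele fractions
    af <- numeric(n)
    af[somatic] <- stats::rbeta(sum(somatic), 4, 8)
    hom <- runif(n_germ) < 0.3
    af[germ_idx] <- ifelse(hom, stats::rbeta(n_germ, 95, 5), stats::rbeta(n_germ, 50, 50))

    tumor_depth <- pmax(1L, rnbinom(n, mu = config$depth_tumor, size = config$depth_size))
    normal_depth <- pmax(1L, rnbinom(n, mu = config$depth_normal, size = config$depth_size))
    tumor_alt <- rbinom(n, tumor_depth, af)
    normal_af <- ifelse(somatic, 0.001, af)
    normal_alt <- rbinom(n, normal_depth, normal_af)

    biased <- runif(n) < config$strand_bias_rate
    p_strand <- ifelse(biased, ifelse(runif(n) < 0.5, 0.97, 0.03), 0.5)
    alt_fwd <- rbinom(n, tumor_alt, p_strand)

    popdb_count <- integer(n)
    leak <- runif(n_germ) < config$popdb_leakage
    popdb_count[germ_idx] <- ifelse(leak, rbinom(n_germ, 1, 0.5), 2L + rpois(n_germ, 5))
    popdb_count[somatic] <- rbinom(sum(somatic), 1, 0.02)

    known_germline <- logical(n)
    known_germline[germ_idx] <- runif(n_germ) < 0.7
    known_germline[somatic] <- runif(sum(somatic)) < 0.002

    zygosity_call <- character(n)
    zygosity_call[germ_idx] <- ifelse(runif(n_germ) < 0.8, "germline", "ambiguous")
    zygosity_call[somatic] <- ifelse(runif(sum(somatic)) < 0.85, "somatic", "ambiguous")

    deleterious_score <- rep(NA_real_, n)
    mis <- consequence == "missense"
    deleterious_score[mis & somatic] <- stats::rbeta(sum(mis & somatic), 8, 1)
    deleterious_score[mis & !somatic] <- stats::rbeta(sum(mis & !somatic), 1.5, 4)

    out <- tibble(
      patient_id = patient_id,
      chrom = panel$chrom[iv],
      pos = pos,
      ref = alleles$ref,
      alt = alleles$alt,
      tumor_ref = as.integer(tumor_depth - tumor_alt),
      tumor_alt = as.integer(tumor_alt),
      normal_ref = as.integer(normal_depth - normal_alt),
      normal_alt = as.integer(normal_alt),
      alt_fwd = as.integer(alt_fwd),
      alt_rev = as.integer(tumor_alt - alt_fwd),
      consequence = consequence,
      popdb_count = as.integer(popdb_count),
      known_germline = known_germline,
      zygosity_call = zygosity_call,
      deleterious_score = deleterious_score,
      truth_somatic = somatic
    )
    # one record per (chrom,pos,ref,alt): drop rare positional collisions
    out <- distinct(out, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .keep_all = TRUE)
    out <- arrange(out, .data$chrom, .data$pos)
    attr(out, "true_tmb") <-
      sum(out$truth_somatic & out$consequence != "noncoding") / mb
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

draw_alleles <- function(consequence) {
  n <- length(consequence)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  ins <- consequence %in% c("frameshift_indel", "inframe_indel")
  if (any(ins)) {
    k <- ifelse(consequence[ins] == "inframe_indel", 3, 1 + (runif(sum(ins)) < 0.5))
    alt[ins] <- paste0(ref[ins], vapply(k, function(m) {
      paste(sample(bases, m, replace = TRUE), collapse = "")
    }, character(1)))
  }
  list(ref = unname(ref), alt = unname(alt))
}

empty_variant_tbl <- function(patient_id = character(0)) {
  tibble(
    patient_id = patient_id[0], chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0),
    tumor_ref = integer(0), tumor_alt = integer(0),
    normal_ref = integer(0), normal_alt = integer(0),
    alt_fwd = integer(0), alt_rev = integer(0),
    consequence = character(0), popdb_count = integer(0),
    known_germline = logical(0), zygosity_call = character(0),
    deleterious_score = numeric(0), truth_somatic = logical(0)
  )
}

#' Simulate the clinical/survival table for pre-assigned strata
#'
#' Overall survival (OS) is the time from therapy start to death from any
#' cause, censored at last follow-up. Survival times are exponential with
#' the configured per-combined-class hazard rate; a `censor_rate` fraction
#' of patients is administratively censored uniformly within their
#' follow-up. Covariates (age, sex, smoking status, pathologic stage,
#' driver mutation status) are drawn from histology-specific marginals
#' matching the published characteristics of a 187-patient cohort (median
#' age 58 ADC / 60 SQCC, 63%/78% male, 20%/29% smokers, 40%/41% stage
#' IIIB, EGFR 43%/4%, KRAS 12%/4%).
#'
#' @param config a [cohort_config()].
#' @param strata tibble with one row per patient: `patient_id`,
#'   `histology` (`"ADC"`/`"SQCC"`), `combined_class` (one of `LM_neg`,
#'   `LM_pos`, `H_pos`, `H_neg`).
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return tibble with covariates, `os_months` and `event` (1 = death).
#' @export
generate_clinical <- function(config, strata, seed = NULL) {
  check_cols(strata, c("patient_id", "histology", "combined_class"), "`strata`")
  if (anyDuplicated(strata$patient_id)) abort("one stratum per patient required")
  bad <- setdiff(unique(strata$combined_class), names(config$hazard_model))
  if (length(bad) > 0) {
    abort(sprintf("unknown combined class: %s", paste(bad, collapse = ", ")))
  }
  if (!all(strata$histology %in% c("ADC", "SQCC"))) {
    abort("histology must be ADC or SQCC")
  }
  run <- function() {
    n <- nrow(strata)
    adc <- strata$histology == "ADC"
    age <- ifelse(adc,
      round(pmin(pmax(rnorm(n, 58, 10), 29), 85)),
      round(pmin(pmax(rnorm(n, 60, 10), 30), 85))
    )
    sex <- ifelse(runif(n) < ifelse(adc, 0.63, 0.78), "male", "female")
    smoking <- ifelse(runif(n) < ifelse(adc, 0.20, 0.29), "smoker", "never")
    stage <- ifelse(runif(n) < ifelse(adc, 0.40, 0.41), "IIIB", "IV")
    u <- runif(n)
    p_egfr <- ifelse(adc, 0.43, 0.04)
    p_kras <- ifelse(adc, 0.12, 0.04)
    mutation <- ifelse(u < p_egfr, "EGFR",
                       ifelse(u < p_egfr + p_kras, "KRAS", "other"))
    rate <- unname(config$hazard_model[strata$combined_class])
    t_death <- rexp(n, rate)
    censored <- runif(n) < config$censor_rate
    os <- ifelse(censored, runif(n) * t_death, t_death)
    tibble(
      patient_id = strata$patient_id,
      histology = strata$histology,
      age = as.integer(age),
      sex = sex,
      smoking = smoking,
      stage = stage,
      mutation_status = mutation,
      os_months = pmax(round(os, 1), 0.1),
      event = as.integer(!censored)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a complete synthetic cohort with ground truth
#'
#' End-to-end simulator: capture panel, per-patient paired variant
#' evidence, PD-L1 TC/IC readouts, and the clinical/survival table, with
#' ground truth (per-variant somatic label, per-patient true TMB and true
#' combined TMB-by-PD-L1 class, true per-class median OS) retained for
#' recovery testing. The true combined class uses cutoffs derived from the
#' cohort's true TMB values (median + SD / median - SD/2) and PD-L1 TC
#' positivity at >= 1%.
#'
#' @param config a [cohort_config()].
#' @param n_intervals,territory_mb panel layout (default 200 intervals,
#'   1.4 Mb of coding territory, a typical large-panel footprint).
#' @return A `synthetic_cohort` list: `panel`, `variants` (all patients,
#'   with `truth_somatic`), `clinical` (includes `tc_pct`, `ic_pct`),
#'   `truth` (per-patient tibble + true cutoffs + true class medians),
#'   `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 7))
#' cohort$clinical
#' @export
generate_cohort <- function(config = cohort_config(),
                            n_intervals = 200, territory_mb = 1.4) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    panel <- generate_panel(n_intervals, territory_mb,
                            seed = child_seed(config$seed, "panel"))
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    n_adc <- round(n * config$histology_mix)
    histology <- rep(c("ADC", "SQCC"), c(n_adc, n - n_adc))

    true_tmb_draw <- rlnorm(n, config$tmb_meanlog, config$tmb_sdlog)
    variants <- vector("list", n)
    true_tmb <- numeric(n)
    for (i in seq_len(n)) {
      variants[[i]] <- generate_variants(panel, config, ids[i],
                                         true_tmb = true_tmb_draw[i])
      true_tmb[i] <- attr(variants[[i]], "true_tmb")
    }
    variants <- bind_rows(variants)

    pdl1 <- draw_pdl1(config, histology)

    cuts <- derive_cutoffs(true_tmb)
    tmb_class_true <- classify_tmb(true_tmb, cuts)
    combined_true <- combine_biomarkers(
      dichotomize_tmb(tmb_class_true), pdl1$tc_pct >= 1
    )
    strata <- tibble(
      patient_id = ids, histology = histology,
      combined_class = as.character(combined_true)
    )
    clinical <- generate_clinical(config, strata)
    clinical$tc_pct <- pdl1$tc_pct
    clinical$ic_pct <- pdl1$ic_pct

    truth <- list(
      patients = tibble(
        patient_id = ids, histology = histology, true_tmb = true_tmb,
        true_tmb_class = tmb_class_true, true_combined_class = combined_true
      ),
      cutoffs = cuts,
      class_median_os = log(2) / config$hazard_model
    )
    structure(
      list(panel = panel, variants = variants, clinical = clinical,
           truth = truth, config = config),
      class = "synthetic_cohort"
    )
  })
}

# Draw TC/IC percentages from the configured category mixture, uniform
# within each category's percentage bin.
draw_pdl1 <- function(config, histology) {
  n <- length(histology)
  tc_bins <- matrix(c(0, 1, 1, 5, 5, 50, 50, 100), nrow = 4, byrow = TRUE)
  ic_bins <- matrix(c(0, 1, 1, 5, 5, 10, 10, 100), nrow = 4, byrow = TRUE)
  draw_one <- function(weights, bins) {
    cat_i <- sample.int(4, 1, prob = weights)
    runif(1, bins[cat_i, 1], bins[cat_i, 2] - 1e-9)
  }
  tc <- numeric(n); ic <- numeric(n)
  for (i in seq_len(n)) {
    m <- config$pdl1_model[[histology[i]]]
    tc[i] <- draw_one(m$tc, tc_bins)
    ic[i] <- draw_one(m$ic, ic_bins)
  }
  list(tc_pct = round(tc, 1), ic_pct = round(ic, 1))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d patients (%d ADC / %d SQCC), %d candidate variants\n",
              nrow(x$clinical), sum(x$clinical$histology == "ADC"),
              sum(x$clinical$histology == "SQCC"), nrow(x$variants)))
  cat(sprintf("  panel: %d intervals, %.2f Mb\n",
              nrow(x$panel), panel_territory_mb(x$panel)))
  cat(sprintf("  true TMB median %.1f mut/Mb; seed %d\n",
              median(x$truth$patients$true_tmb), x$config$seed))
  invisible(x)
}
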