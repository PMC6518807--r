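#' Configuration for the synthetic NSCLC cohort generator
#'
#' Bundles every tunable of the simulator with validated defaults that
#' emulate a 187-patient two-histology NSCLC cohort: 73% adenocarcinoma
#' (ADC) vs 27% squamous cell carcinoma (SQCC); log-normal per-Mb TMB with
#' median 8 mutations/Mb; PD-L1 TC/IC category mixtures matching published
#' four-category frequencies per histology; covariate marginals (age, sex,
#' smoking, stage, driver mutation) matching the printed characteristics
#' table; and exponential overall-survival hazards per combined
#' TMB-by-PD-L1 class with medians 32 (low/moderate TMB, PD-L1 negative),
#' 8.5 (low/moderate TMB, PD-L1 positive), 6 (high TMB, PD-L1 positive)
#' and 12 (high TMB, PD-L1 negative) months.
#'
#' @param n_patients cohort size.
#' @param histology_mix proportion of ADC patients (remainder SQCC).
#' @param tmb_meanlog,tmb_sdlog log-normal parameters of the true per-Mb
#'   TMB distribution.
#' @param somatic_fraction expected proportion of candidate variants that
#'   are truly somatic (0 and 1 allowed as degenerate boundaries).
#' @param depth_tumor,depth_normal mean sequencing depths.
#' @param depth_size negative-binomial size (overdispersion) for depths.
#' @param strand_bias_rate proportion of variants simulated with a skewed
#'   strand profile (sequencing-artifact signature).
#' @param popdb_leakage proportion of germline variants that escape the
#'   population-database annotation (observation count <= 1), exercising
#'   the filter's false-negative path.
#' @param pdl1_model list with elements `ADC` and `SQCC`, each a list with
#'   numeric weight vectors `tc` and `ic` over categories 0-3 (must sum
#'   to 1 within 1e-6).
#' @param hazard_model named numeric vector of exponential hazard rates
#'   (events/month, strictly positive) for classes `LM_neg`, `LM_pos`,
#'   `H_pos`, `H_neg`.
#' @param censor_rate proportion of patients administratively censored.
#' @param seed integer seed; identical seed + config give byte-identical
#'   outputs.
#' @return A validated `cohort_config` list.
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 42)
#' cfg$hazard_model
#' @export
cohort_config <- function(n_patients = 187,
                          histology_mix = 136 / 187,
                          tmb_meanlog = log(8),
                          tmb_sdlog = 0.8,
                          somatic_fraction = 0.5,
                          depth_tumor = 300,
                          depth_normal = 200,
                          depth_size = 20,
                          strand_bias_rate = 0.05,
                          popdb_leakage = 0.05,
                          pdl1_model = default_pdl1_model(),
                          hazard_model = c(
                            LM_neg = log(2) / 32,
                            LM_pos = log(2) / 8.5,
                            H_pos = log(2) / 6,
                            H_neg = log(2) / 12
                          ),
                          censor_rate = 0.2,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1")
  }
  check_prob(histology_mix, "histology_mix")
  check_prob(somatic_fraction, "somatic_fraction")
  check_prob(strand_bias_rate, "strand_bias_rate")
  check_prob(popdb_leakage, "popdb_leakage")
  check_prob(censor_rate, "censor_rate")
  if (!is.numeric(tmb_sdlog) || tmb_sdlog < 0) abort("`tmb_sdlog` must be >= 0")
  for (d in c(depth_tumor, depth_normal, depth_size)) {
    if (!is.numeric(d) || d <= 0) abort("depth parameters must be positive")
  }
  classes <- c("LM_neg", "LM_pos", "H_pos", "H_neg")
  if (!all(classes %in% names(hazard_model))) {
    abort("`hazard_model` must name rates for LM_neg, LM_pos, H_pos, H_neg")
  }
  if (any(!is.finite(hazard_model)) || any(hazard_model <= 0)) {
    abort("hazard rates must be strictly positive")
  }
  for (h in c("ADC", "SQCC")) {
    for (comp in c("tc", "ic")) {
      w <- pdl1_model[[h]][[comp]]
      if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-6) {
        abort(sprintf(
          "pdl1_model$%s$%s must be 4 non-negative weights summing to 1", h, comp
        ))
      }
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      histology_mix = histology_mix,
      tmb_meanlog = tmb_meanlog,
      tmb_sdlog = tmb_sdlog,
      somatic_fraction = somatic_fraction,
      depth_tumor = depth_tumor,
      depth_normal = depth_normal,
      depth_size = depth_size,
      strand_bias_rate = strand_bias_rate,
      popdb_leakage = popdb_leakage,
      pdl1_model = pdl1_model,
      hazard_model = hazard_model[classes],
      censor_rate = censor_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default PD-L1 category mixture per histology
#'
#' Four-category (negative/weak/moderate/strong) weights for tumor cells
#' (TC) and immune cells (IC), matching published frequencies: ADC TC
#' 63/10/7/20%, ADC IC 65/10/5/20%, SQCC TC 45/14/14/27%, SQCC IC
#' 43/29/4/24%.
#'
#' @return nested list `list(ADC = list(tc=, ic=), SQCC = ...)`.
#' @export
default_pdl1_model <- function() {
  list(
    ADC = list(tc = c(0.63, 0.10, 0.07, 0.20), ic = c(0.65, 0.10, 0.05, 0.20)),
    SQCC = list(tc = c(0.45, 0.14, 0.14, 0.27), ic = c(0.43, 0.29, 0.04, 0.24))
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n_patients: %d (ADC share %.2f)\n", x$n_patients, x$histology_mix))
  cat(sprintf("  true TMB ~ lognormal(meanlog=%.3f, sdlog=%.3f)\n",
              x$tmb_meanlog, x$tmb_sdlog))
  cat(sprintf("  somatic fraction %.2f, strand-bias rate %.2f\n",
              x$somatic_fraction, x$strand_bias_rate))
  cat(sprintf("  class medians (months): %s\n",
              paste(sprintf("%s=%.1f", names(x$hazard_model),
                            log(2) / x$hazard_model), collapse = ", ")))
  cat(sprintf("  censor rate %.2f, seed %d\n", x$censor_rate, x$seed))
  invisible(x)
}
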