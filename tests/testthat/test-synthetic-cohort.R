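test_that("cohort config validates proportions, weights and hazards", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(censor_rate = 1.2), "probability")
  expect_error(cohort_config(hazard_model = c(LM_neg = 0, LM_pos = 1,
                                              H_pos = 1, H_neg = 1)),
               "strictly positive")
  bad <- default_pdl1_model()
  bad$ADC$tc <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohort_config(pdl1_model = bad), "summing to 1")
})

test_that("variant simulation respects panel bounds, labels and boundaries", {
  panel <- generate_panel(20, 0.5, seed = 2)
  cfg <- cohort_config(n_patients = 1, seed = 5)
  v <- generate_variants(panel, cfg, "P1", true_tmb = 20, seed = 9)
  expect_gt(nrow(v), 0)
  expect_true(all(panel_contains(panel, v$chrom, v$pos)))
  expect_true(all(v$tumor_ref + v$tumor_alt >= 1))
  expect_true(all(v$alt_fwd + v$alt_rev == v$tumor_alt))
  # conservation: every candidate is labeled somatic or germline
  expect_equal(sum(v$truth_somatic) + sum(!v$truth_somatic), nrow(v))

  all_germ <- generate_variants(panel, cohort_config(somatic_fraction = 0),
                                "P1", true_tmb = 20, seed = 9)
  expect_gt(nrow(all_germ), 0)
  expect_true(all(!all_germ$truth_somatic))

  all_som <- generate_variants(panel, cohort_config(somatic_fraction = 1),
                               "P1", true_tmb = 20, seed = 9)
  expect_true(all(all_som$truth_somatic))

  expect_identical(generate_variants(panel, cfg, "P1", true_tmb = 8, seed = 4),
                   generate_variants(panel, cfg, "P1", true_tmb = 8, seed = 4))
})

test_that("pure somatic deep-coverage cohorts pass the filter chain nearly completely", {
  panel <- generate_panel(20, 1.4, seed = 2)
  cfg <- cohort_config(somatic_fraction = 1, strand_bias_rate = 0,
                       depth_tumor = 400, depth_normal = 300)
  v <- generate_variants(panel, cfg, "P1", true_tmb = 60, seed = 21)
  res <- apply_filters(v, filter_config(), panel)
  coding_somatic <- res$consequence != "noncoding"
  expect_gt(mean(res$kept[coding_somatic]), 0.95)
})

test_that("clinical generation honors strata, hazards and censoring", {
  cfg <- cohort_config(seed = 1, censor_rate = 0)
  strata <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:200),
    histology = rep(c("ADC", "SQCC"), 100),
    combined_class = rep(c("LM_neg", "H_pos"), each = 100)
  )
  cl <- generate_clinical(cfg, strata, seed = 2)
  expect_equal(nrow(cl), 200)
  expect_true(all(cl$event == 1))
  expect_true(all(cl$os_months > 0))
  expect_true(all(cl$sex %in% c("male", "female")))
  expect_true(all(cl$mutation_status %in% c("EGFR", "KRAS", "other")))

  # all-censored boundary: KM median not reached
  cl_cens <- generate_clinical(cohort_config(censor_rate = 1), strata, seed = 2)
  expect_true(all(cl_cens$event == 0))
  expect_true(is.na(km_median(km_estimate(cl_cens))))

  expect_error(
    generate_clinical(cfg, tibble::tibble(
      patient_id = "P1", histology = "ADC", combined_class = "bogus"
    )),
    "unknown combined class"
  )
})

test_that("exponential survival recovers closed-form medians", {
  # median of Exp(rate) is ln2/rate; single class, rate ln2/32, no censoring
  cfg <- cohort_config(censor_rate = 0,
                       hazard_model = c(LM_neg = log(2) / 32, LM_pos = 1,
                                        H_pos = 1, H_neg = 1))
  strata <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:1000), histology = "ADC",
    combined_class = "LM_neg"
  )
  cl <- generate_clinical(cfg, strata, seed = 33)
  expect_equal(unname(km_median(km_estimate(cl))), 32, tolerance = 0.1)

  # hazard ratio 4 between two classes -> KM median ratio ~ 4
  cfg2 <- cohort_config(censor_rate = 0,
                        hazard_model = c(LM_neg = log(2) / 32,
                                         LM_pos = log(2) / 8,
                                         H_pos = 1, H_neg = 1))
  strata2 <- tibble::tibble(
    patient_id = sprintf("Q%04d", 1:1000), histology = "ADC",
    combined_class = rep(c("LM_neg", "LM_pos"), each = 500)
  )
  cl2 <- generate_clinical(cfg2, strata2, seed = 12)
  cl2$group <- rep(c("slow", "fast"), each = 500)
  med <- km_median(km_estimate(cl2, group = "group"))
  expect_equal(unname(med["slow"] / med["fast"]), 4, tolerance = 0.2)
})

test_that("whole-cohort generation is deterministic and self-consistent", {
  cfg <- cohort_config(n_patients = 30, seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$panel, c2$panel)

  # ground truth invariant: true TMB = somatic coding count / territory
  mb <- panel_territory_mb(c1$panel)
  counted <- dplyr::count(
    dplyr::filter(c1$variants, truth_somatic, consequence != "noncoding"),
    patient_id
  )
  tr <- merge(c1$truth$patients, counted, by = "patient_id", all.x = TRUE)
  tr$n[is.na(tr$n)] <- 0
  expect_equal(tr$true_tmb, tr$n / mb, tolerance = 1e-12)
})

test_that("pipeline TMB tracks true TMB within 10% at depth >= 100x", {
  cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 101))
  fc <- filter_cohort(cohort$variants, filter_config(), cohort$panel)
  tmb <- compute_tmb(fc$retained, cohort$panel,
                     patients = cohort$clinical$patient_id)
  j <- merge(tmb, cohort$truth$patients, by = "patient_id")
  rel_err <- abs(j$tmb - j$true_tmb) / pmax(j$true_tmb, 0.5)
  expect_lt(mean(rel_err), 0.10)
})
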