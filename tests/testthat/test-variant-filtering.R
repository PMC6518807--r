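test_that("somatic exact test matches enumeration and Fisher oracles", {
  # enumeration oracle: hypergeometric tail summed from binomial coefficients
  enum_tail <- function(ta, tr, na_, nr) {
    td <- ta + tr; m <- ta + na_; n_ref <- tr + nr
    ks <- ta:min(td, m)
    sum(choose(m, ks) * choose(n_ref, td - ks)) / choose(m + n_ref, td)
  }
  expect_equal(somatic_p(10, 10, 20, 0), enum_tail(10, 10, 0, 20))
  expect_lt(somatic_p(10, 10, 20, 0), 0.05)

  withr::with_seed(42, {
    for (i in 1:50) {
      tr <- sample(0:25, 1); ta <- sample(0:25, 1)
      nr <- sample(0:25, 1); na_ <- sample(0:25, 1)
      if (tr + ta == 0 || nr + na_ == 0) next
      p <- somatic_p(tr, ta, nr, na_)
      expect_equal(p, enum_tail(ta, tr, na_, nr), tolerance = 1e-12)
      ft <- fisher.test(matrix(c(ta, tr, na_, nr), 2, byrow = TRUE),
                        alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    }
  })
})

test_that("somatic exact test boundaries behave", {
  # identical allele fractions: no enrichment
  expect_gte(somatic_p(10, 5, 10, 5), 0.5)
  # no tumor alt reads: tail probability is 1
  expect_equal(somatic_p(10, 0, 5, 3), 1)
  expect_error(somatic_p(0, 0, 10, 2), "zero read depth")
  # two-sided matches fisher.test
  expect_equal(somatic_p(5, 9, 12, 2, alternative = "two.sided"),
               fisher.test(matrix(c(9, 5, 2, 12), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("strand-bias fraction and keep rule follow the <90% convention", {
  expect_equal(strand_bias_fraction(5, 5), 0.5)
  expect_equal(strand_bias_fraction(9, 1), 0.9)
  expect_equal(strand_bias_fraction(89, 11), 0.89)
  expect_error(strand_bias_fraction(0, 0), "undefined")

  panel <- toy_panel()
  cfg <- filter_config()
  kept_89 <- apply_filters(toy_variant(alt_fwd = 89L, alt_rev = 11L,
                                       tumor_ref = 60L, tumor_alt = 100L),
                           cfg, panel)
  expect_true(kept_89$kept)
  dropped_90 <- apply_filters(toy_variant(alt_fwd = 9L, alt_rev = 1L,
                                          tumor_ref = 90L, tumor_alt = 10L),
                              cfg, panel)
  expect_false(dropped_90$kept)
  expect_match(dropped_90$reasons, "strand_bias")
})

test_that("individual exclusion rules fire with the documented reasons", {
  panel <- toy_panel()
  cfg <- filter_config()

  allpass <- apply_filters(toy_variant(), cfg, panel)
  expect_true(allpass$kept)
  expect_identical(allpass$reasons, "")

  popdb <- apply_filters(toy_variant(popdb_count = 2L), cfg, panel)
  expect_false(popdb$kept)
  expect_identical(popdb$reasons, "popdb_germline")

  lowN <- apply_filters(toy_variant(normal_ref = 7L, normal_alt = 0L), cfg, panel)
  expect_false(lowN$kept)
  expect_match(lowN$reasons, "coverage_normal")

  benign <- apply_filters(toy_variant(deleterious_score = 0.40), cfg, panel)
  expect_false(benign$kept)
  expect_identical(benign$reasons, "benign")
  # score exactly at the threshold is NOT benign (strict <)
  expect_true(apply_filters(toy_variant(deleterious_score = 0.452),
                            cfg, panel)$kept)

  # the benign rule is vacuous outside missense
  expect_true(apply_filters(
    toy_variant(consequence = "synonymous", deleterious_score = NA_real_),
    cfg, panel
  )$kept)

  dbsnp <- apply_filters(toy_variant(known_germline = TRUE), cfg, panel)
  expect_identical(dbsnp$reasons, "dbsnp_germline")
  zyg <- apply_filters(toy_variant(zygosity_call = "germline"), cfg, panel)
  expect_identical(zyg$reasons, "zygosity_germline")
  nc <- apply_filters(toy_variant(consequence = "noncoding"), cfg, panel)
  expect_identical(nc$reasons, "noncoding")
  off <- apply_filters(toy_variant(pos = 2000000L), cfg, panel)
  expect_identical(off$reasons, "noncoding")

  # synonymous dropped only when the config says so
  syn_cfg <- filter_config(count_synonymous_for_tmb = FALSE)
  syn <- apply_filters(toy_variant(consequence = "synonymous",
                                   deleterious_score = NA_real_),
                       syn_cfg, panel)
  expect_identical(syn$reasons, "synonymous")
})

test_that("all filters are evaluated without short-circuiting", {
  panel <- toy_panel()
  v <- toy_variant(
    normal_ref = 3L, normal_alt = 0L,       # coverage_normal
    tumor_ref = 2L, tumor_alt = 1L,         # coverage_tumor (+ weak p)
    alt_fwd = 1L, alt_rev = 0L,             # strand bias 1.0
    popdb_count = 5L, known_germline = TRUE,
    zygosity_call = "germline", deleterious_score = 0.1
  )
  res <- apply_filters(v, filter_config(), panel)
  got <- strsplit(res$reasons, ",")[[1]]
  expect_setequal(got, c("coverage_normal", "coverage_tumor", "not_somatic_p",
                         "strand_bias", "popdb_germline", "dbsnp_germline",
                         "zygosity_germline", "benign"))
  # reasons come in fixed chain order
  expect_identical(got, intersect(
    c("coverage_normal", "coverage_tumor", "not_somatic_p", "strand_bias",
      "noncoding", "popdb_germline", "dbsnp_germline", "zygosity_germline",
      "benign", "synonymous"), got
  ))
})

test_that("tightening any threshold never increases the retained count", {
  panel <- toy_panel()
  withr::with_seed(7, {
    vs <- dplyr::bind_rows(lapply(1:150, function(i) {
      random_variant(patient = sprintf("P%03d", i), pos = 1000L + i)
    }))
  })
  base_cfg <- filter_config()
  base_kept <- sum(apply_filters(vs, base_cfg, panel)$kept)
  tighter <- list(
    filter_config(min_normal_depth = 20),
    filter_config(min_tumor_depth = 20),
    filter_config(somatic_p_threshold = 0.01),
    filter_config(strand_bias_max = 0.7),
    filter_config(popdb_max_count = 0),
    filter_config(benign_score_threshold = 0.8),
    filter_config(count_synonymous_for_tmb = FALSE)
  )
  for (cfg in tighter) {
    expect_lte(sum(apply_filters(vs, cfg, panel)$kept), base_kept)
  }
})

test_that("filter chain agrees with an independent brute-force evaluation", {
  panel <- toy_panel()
  cfgs <- list(
    filter_config(),
    filter_config(p_inclusive = FALSE, count_synonymous_for_tmb = FALSE),
    filter_config(strand_bias_max = 0.8, popdb_max_count = 0)
  )
  withr::with_seed(123, {
    for (rep in 1:40) {
      cfg <- cfgs[[sample(3, 1)]]
      n <- sample(1:20, 1)
      vs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        random_variant(pos = 100L * i)
      }))
      res <- apply_filters(vs, cfg, panel)
      for (i in seq_len(n)) {
        oracle <- brute_force_verdict(vs[i, ], cfg, 0, 1e6)
        expect_identical(res$kept[i], oracle$kept)
        expect_identical(res$reasons[i], paste(oracle$reasons, collapse = ","))
      }
    }
  })
})

test_that("cohort filtering conserves candidates and audits every variant", {
  panel <- toy_panel()
  empty <- filter_cohort(toy_variant()[0, ], filter_config(), panel)
  expect_equal(nrow(empty$audit), 0)
  expect_equal(nrow(empty$retained), 0)

  dup <- dplyr::bind_rows(toy_variant(), toy_variant())
  expect_error(filter_cohort(dup, filter_config(), panel), "duplicate")

  # hand-traced toy patient: exactly 4 of 10 candidates survive
  vs <- dplyr::bind_rows(
    toy_variant(pos = 101L),                                  # keep 1
    toy_variant(pos = 102L, consequence = "synonymous",
                deleterious_score = NA_real_),                # keep 2
    toy_variant(pos = 103L, consequence = "frameshift_indel",
                alt = "AT", deleterious_score = NA_real_),    # keep 3
    toy_variant(pos = 104L, tumor_alt = 35L, tumor_ref = 65L,
                alt_fwd = 20L, alt_rev = 15L),                # keep 4
    toy_variant(pos = 105L, popdb_count = 3L),                # popdb
    toy_variant(pos = 106L, known_germline = TRUE),           # dbSNP
    toy_variant(pos = 107L, zygosity_call = "germline"),      # zygosity
    toy_variant(pos = 108L, deleterious_score = 0.2),         # benign
    toy_variant(pos = 109L, normal_ref = 5L, normal_alt = 0L),# coverage
    toy_variant(pos = 110L, tumor_alt = 2L, tumor_ref = 98L,
                alt_fwd = 2L, alt_rev = 0L)                   # not somatic
  )
  fc <- filter_cohort(vs, filter_config(), panel)
  expect_equal(nrow(fc$audit), 10)
  expect_equal(nrow(fc$retained), 4)
  expect_setequal(fc$retained$pos, 101:104)
  expect_equal(fc$summary$n_kept + fc$summary$n_dropped, fc$summary$n_candidates)
  expect_equal(nrow(tidy(fc)), 10)
})

test_that("filter chain recovers planted somatic labels on synthetic cohorts", {
  cohort <- generate_cohort(cohort_config(n_patients = 40, seed = 55))
  fc <- filter_cohort(cohort$variants, filter_config(), cohort$panel)
  aud <- fc$audit
  coding_somatic <- aud$truth_somatic & aud$consequence != "noncoding"
  sens <- mean(aud$kept[coding_somatic])
  spec <- mean(!aud$kept[!aud$truth_somatic])
  expect_gt(sens, 0.85)  # losses: strand-bias artifacts + annotation noise
  expect_gt(spec, 0.98)
})
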