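#' Run the complete combined-biomarker analysis
#'
#' Ties every stage together for a cohort: somatic filtering and TMB
#' quantification (when variant evidence and a panel are supplied, or a
#' precomputed TMB table), data-adaptive TMB cutoffs and classes, PD-L1
#' TC/IC scoring and frequency tables, combined TMB-by-PD-L1 strata and
#' overlap summaries, characteristic tables with per-row association
#' tests, Kaplan-Meier curves and log-rank tests per stratification
#' (EGFR status, PD-L1 TC positivity, dichotomized TMB, combined class),
#' TMB-vs-PD-L1 rank correlation and Kruskal-Wallis/Dunn comparisons —
#' all per histology. Histologies absent from the cohort are skipped
#' with a notice. Given identical inputs the report is deterministic.
#'
#' @param clinical clinical table (see [read_clinical()] for the schema).
#' @param variants optional candidate-variant tibble across patients.
#' @param panel `tmb_panel`; required with `variants`.
#' @param tmb_table precomputed per-patient TMB tibble (`patient_id`,
#'   `tmb`); used when `variants` is `NULL`.
#' @param filter_cfg a [filter_config()].
#' @param exclude_h_neg drop the high-TMB/PD-L1-negative class from the
#'   combined-class survival comparison (default `TRUE`, mirroring the
#'   conventional three-class presentation; the class is still assigned
#'   and reported everywhere else).
#' @return A `biomarker_report` list; see [glance.biomarker_report()].
#' @export
run_full_analysis <- function(clinical, variants = NULL, panel = NULL,
                              tmb_table = NULL,
                              filter_cfg = filter_config(),
                              exclude_h_neg = TRUE) {
  clinical <- validate_clinical(clinical)
  filter_summary <- NULL
  if (!is.null(variants)) {
    if (is.null(panel)) abort("`panel` is required when `variants` are supplied")
    fc <- filter_cohort(variants, filter_cfg, panel)
    filter_summary <- fc$summary
    tmb_table <- compute_tmb(fc$retained, panel,
                             patients = clinical$patient_id)
  }
  if (is.null(tmb_table)) {
    abort("supply either `variants` + `panel` or a precomputed `tmb_table`")
  }
  check_cols(tmb_table, c("patient_id", "tmb"), "`tmb_table`")

  cutoffs <- derive_cutoffs(tmb_table$tmb, sd_method = filter_cfg$sd_method)
  tmb_table <- mutate(tmb_table, tmb_class = classify_tmb(.data$tmb, cutoffs))

  cohort <- clinical |>
    score_pdl1() |>
    left_join(select(tmb_table, "patient_id", "tmb", "tmb_class"),
              by = "patient_id") |>
    assign_strata()

  histologies <- intersect(c("ADC", "SQCC"), unique(cohort$histology))
  skipped <- setdiff(c("ADC", "SQCC"), histologies)
  if (length(skipped) > 0) {
    inform(sprintf("no %s patients: sections skipped",
                   paste(skipped, collapse = "/")))
  }

  per_hist <- function(f) {
    setNames(lapply(histologies, function(h) {
      f(filter(cohort, .data$histology == h))
    }), histologies)
  }

  frequencies <- per_hist(function(d) {
    list(
      tc4 = pdl1_frequency_table(d, "tc", 4),
      tc2 = pdl1_frequency_table(d, "tc", 2),
      ic4 = pdl1_frequency_table(d, "ic", 4),
      ic2 = pdl1_frequency_table(d, "ic", 2)
    )
  })

  characteristics <- per_hist(function(d) characteristics_table(d))

  survival_res <- per_hist(function(d) {
    res <- list()
    strats <- list(
      egfr = factor(if_else(d$mutation_status == "EGFR", "EGFR mutant", "wildtype")),
      pdl1_tc = factor(if_else(d$tc_positive, "PD-L1 positive", "PD-L1 negative")),
      tmb = d$tmb_binary
    )
    cc <- d
    if (exclude_h_neg) cc <- filter(cc, .data$combined_class != "H_neg")
    strats$combined <- droplevels(factor(cc$combined_class))
    data_for <- list(d, d, d, cc)
    for (i in seq_along(strats)) {
      nm <- names(strats)[i]
      dd <- mutate(data_for[[i]], .group = strats[[i]])
      if (nlevels(droplevels(dd$.group)) < 2) {
        inform(sprintf("stratification `%s`: fewer than 2 groups, skipped", nm))
        next
      }
      km <- km_estimate(dd, group = ".group")
      res[[nm]] <- list(
        km = km,
        medians = glance(km),
        logrank = logrank_test(dd, group = ".group")
      )
    }
    res
  })

  overlap <- list()
  subgroups <- list(
    ADC_wildtype = filter(cohort, .data$histology == "ADC",
                          .data$mutation_status != "EGFR"),
    ADC_EGFR_mutant = filter(cohort, .data$histology == "ADC",
                             .data$mutation_status == "EGFR"),
    SQCC = filter(cohort, .data$histology == "SQCC")
  )
  for (nm in names(subgroups)) {
    sg <- subgroups[[nm]]
    if (nrow(sg) == 0) next
    overlap[[nm]] <- overlap_summary(sg, total_n = nrow(cohort))
  }

  correlation <- per_hist(function(d) spearman_corr(d$tmb, d$tc_pct))
  tmb_by_grade <- per_hist(function(d) {
    if (nlevels(droplevels(d$tc_grade)) < 2) return(NULL)
    kruskal_dunn(mutate(d, value = .data$tmb, group = droplevels(.data$tc_grade)))
  })

  structure(
    list(
      cohort = cohort,
      cutoffs = cutoffs,
      tmb = tmb_table,
      filter_summary = filter_summary,
      frequencies = frequencies,
      characteristics = characteristics,
      survival = survival_res,
      overlap = overlap,
      correlation = correlation,
      tmb_by_grade = tmb_by_grade,
      settings = list(filter_cfg = filter_cfg, exclude_h_neg = exclude_h_neg)
    ),
    class = "biomarker_report"
  )
}

# Characteristics-by-PD-L1 and by-TMB table for one histology: each
# covariate row cross-tabulated against TC positivity and against the
# dichotomized TMB class, with the association test per row.
characteristics_table <- function(d) {
  age_cut <- round(median(d$age))
  covars <- list(
    age = factor(if_else(d$age < age_cut,
                         sprintf("<%g", age_cut), sprintf(">=%g", age_cut))),
    sex = factor(d$sex),
    smoking = factor(d$smoking),
    stage = factor(d$stage),
    mutation_status = factor(d$mutation_status)
  )
  outcomes <- list(
    pdl1_tc = factor(if_else(d$tc_positive, "any_pos", "negative"),
                     levels = c("negative", "any_pos")),
    pdl1_ic = factor(if_else(d$ic_positive, "any_pos", "negative"),
                     levels = c("negative", "any_pos")),
    tmb = d$tmb_binary
  )
  out <- list()
  for (oc in names(outcomes)) {
    for (cv in names(covars)) {
      tab <- table(covars[[cv]], outcomes[[oc]])
      res <- tryCatch(contingency_test(tab),
                      error = function(e) tibble(p_value = NA_real_,
                                                 statistic = NA_real_,
                                                 method_used = "degenerate"))
      cells <- as_tibble(as.data.frame(tab)) |>
        rename(level = "Var1", outcome = "Var2", count = "Freq")
      out[[paste(oc, cv, sep = ".")]] <- mutate(
        cells, outcome_var = oc, covariate = cv,
        p_value = res$p_value, method_used = res$method_used
      )
    }
  }
  bind_rows(out) |>
    select("outcome_var", "covariate", "level", "outcome", "count",
           "p_value", "method_used")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("<biomarker_report>\n")
  cat(sprintf("  %d patients; TMB cutoffs: High >= %.2f, Low < %.2f (median %.2f)\n",
              nrow(x$cohort), x$cutoffs$high_cutoff, x$cutoffs$low_cutoff,
              x$cutoffs$median))
  for (h in names(x$frequencies)) {
    f2 <- x$frequencies[[h]]$tc2
    cat(sprintf("  %s: PD-L1 TC positive %d%% (%d/%d)\n", h,
                f2$pct[f2$category == "positive"],
                f2$count[f2$category == "positive"],
                sum(f2$count)))
  }
  for (h in names(x$survival)) {
    if (!is.null(x$survival[[h]]$combined)) {
      lr <- x$survival[[h]]$combined$logrank
      cat(sprintf("  %s combined-class log-rank: chi2 = %.2f, p = %.3g\n",
                  h, lr$statistic, lr$p_value))
    }
  }
  invisible(x)
}

#' One-row summary of a biomarker report
#'
#' @param x a `biomarker_report`.
#' @param ... unused.
#' @return tibble with cohort size, TMB median and cutoffs, per-histology
#'   PD-L1 TC positivity percentages and combined-class log-rank p-values
#'   (where computed).
#' @method glance biomarker_report
#' @export
glance.biomarker_report <- function(x, ...) {
  row <- tibble(
    n_patients = nrow(x$cohort),
    tmb_median = x$cutoffs$median,
    tmb_high_cutoff = x$cutoffs$high_cutoff,
    tmb_low_cutoff = x$cutoffs$low_cutoff
  )
  for (h in names(x$frequencies)) {
    f2 <- x$frequencies[[h]]$tc2
    row[[paste0("pdl1_tc_pos_pct_", h)]] <-
      f2$pct[f2$category == "positive"]
  }
  for (h in names(x$survival)) {
    if (!is.null(x$survival[[h]]$combined)) {
      row[[paste0("combined_logrank_p_", h)]] <-
        x$survival[[h]]$combined$logrank$p_value
    }
  }
  row
}

#' Write a report bundle to disk
#'
#' Emits the tabular pieces of a `biomarker_report` as TSV plus a JSON
#' summary (cutoffs, overlap, log-rank p-values, settings echo).
#'
#' @param report a `biomarker_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "biomarker_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$cohort, file.path(dir, "cohort.tsv"))
  readr::write_tsv(report$tmb, file.path(dir, "tmb.tsv"))
  freq <- bind_rows(lapply(names(report$frequencies), function(h) {
    bind_rows(lapply(names(report$frequencies[[h]]), function(k) {
      mutate(report$frequencies[[h]][[k]], histology = h, table = k)
    }))
  }))
  readr::write_tsv(freq, file.path(dir, "pdl1_frequencies.tsv"))
  readr::write_tsv(bind_rows(report$characteristics, .id = "histology"),
                   file.path(dir, "characteristics.tsv"))
  if (!is.null(report$filter_summary)) {
    readr::write_tsv(report$filter_summary, file.path(dir, "filter_summary.tsv"))
  }
  surv <- list()
  for (h in names(report$survival)) {
    for (nm in names(report$survival[[h]])) {
      s <- report$survival[[h]][[nm]]
      surv[[paste(h, nm, sep = ".")]] <- list(
        medians = s$medians,
        logrank = as.list(s$logrank)
      )
    }
  }
  jsonlite::write_json(
    list(
      cutoffs = unclass(report$cutoffs),
      survival = surv,
      overlap = report$overlap,
      correlation = report$correlation,
      settings = list(
        filter_config = unclass(report$settings$filter_cfg),
        exclude_h_neg = report$settings$exclude_h_neg
      )
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  invisible(dir)
}
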