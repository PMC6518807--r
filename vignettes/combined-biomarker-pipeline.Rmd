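---
title: "Methods: the combined TMB + PD-L1 biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the combined TMB + PD-L1 biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbpdl1)
```

## What the pipeline does

tmbpdl1 implements, end to end, a combined-biomarker analysis for
non-small cell lung cancer (NSCLC) of the kind used to relate tumor
mutational burden (TMB) and PD-L1 expression to overall survival under
chemotherapy and targeted therapy. The stages are:

1. **Paired somatic filtering** of candidate variants from count-level
   tumor/normal evidence;
2. **TMB quantification**, normalizing the retained mutation count by the
   panel's coding territory, with data-adaptive trichotomization;
3. **PD-L1 scoring** of tumor-cell (TC) and immune-cell (IC) staining
   percentages into semiquantitative ladders;
4. **Combined stratification** of dichotomized TMB with PD-L1 TC
   positivity;
5. **Survival and association statistics** (Kaplan-Meier, log-rank,
   chi-square/Fisher, Spearman, Kruskal-Wallis with Dunn's pairwise
   comparisons).

Because patient-level data of this kind are generally unavailable, the
package also ships a synthetic cohort generator with known ground truth;
every stage is tested against that truth.

## The somatic filter chain

Each candidate variant carries paired read counts (tumor ref/alt, normal
ref/alt), tumor strand counts for the alt allele, a consequence class,
and annotation fields that stand in for external databases: a
population-database observation count (ExAC-style), a known-germline
flag (dbSNP-style), a somatic/germline zygosity-algorithm call, and a
PolyPhen-2-style deleteriousness score in [0, 1]. Annotations are
*inputs*: the package does not query live databases.

The chain evaluates, in fixed order, with every rule applied to every
variant (no short-circuiting, so the audit trail is complete):

| filter | rule (defaults) |
|---|---|
| normal coverage | normal depth ≥ 8× |
| tumor coverage | tumor depth ≥ 6× |
| somatic test | one-sided exact test p ≤ 0.05 |
| strand bias | majority-strand fraction < 0.90 |
| coding/panel | consequence not non-coding, position inside the panel |
| population DB | observation count ≤ 1 (exclude ≥ 2) |
| known germline | flag unset |
| zygosity | algorithm call not "germline" |
| benign | missense score ≥ 0.452 |

Design choices that were genuinely open, and how they were settled:

* **Coverage thresholds.** The two minimums are assigned 8× to the
  normal (peripheral-blood) sample and 6× to the tumor sample; both are
  configuration keys, so the opposite reading is one argument away.
* **Somatic test.** The paired-caller test is the one-sided Fisher exact
  test on the 2×2 (tumor vs normal) × (ref vs alt) table, with the
  alternative that the tumor alt fraction exceeds the normal's. It is
  implemented directly from the hypergeometric tail
  (`phyper`) for vectorized evaluation; a two-sided variant is available
  by configuration. The 0.05 threshold is inclusive (p ≤ 0.05 calls the
  site somatic) by default, with `p_inclusive = FALSE` exposing the
  strict reading.
* **Strand bias.** "Kept below 90% strand bias" is read as: the fraction
  of tumor alt reads on the majority strand must be strictly below 0.90.
  This is the only reading under which balanced variants pass. Variants
  with no assessable strand evidence fail the rule by default
  (`strand_missing = "pass"` relaxes this).
* **Benign score.** The deleteriousness score is defined for missense
  changes only; indels, synonymous and truncating variants pass the
  benign rule vacuously.
* **Synonymous variants** are *retained* for TMB by default
  (`count_synonymous_for_tmb = TRUE`): counting synonymous events
  reduces sampling noise in a small panel. Workflows that keep only
  nonsynonymous exonic mutations are reproduced by setting the flag to
  `FALSE`; both readings are legitimate and the package exposes the
  choice rather than hiding it.
* **No multiple-testing correction** is applied across sites, matching
  the single-site calling convention of paired callers.
* **Coordinates.** Panels are BED-style 0-based half-open; variants are
  VCF-style 1-based. The conversion lives in one routine
  (`panel_contains()`); a 0-based interval [s, e) contains 1-based
  positions s+1 … e.

## TMB quantification and trichotomization

For patient *i* with *m<sub>i</sub>* retained mutations on a panel of
*L* megabases of coding territory,

TMB<sub>i</sub> = *m<sub>i</sub>* / *L*   [mutations/Mb].

Multi-allelic sites count once per passing alt allele. The cohort is
then split into Low / Moderate / High with cutoffs derived from the
pooled TMB distribution (both histologies together, since a single
cutoff pair should apply to the whole cohort):

* high/moderate boundary: median + SD,
* moderate/low boundary: median − SD/2, floored at 0.

SD is the sample standard deviation (n−1), the usual cohort convention;
a population-SD variant is available for sensitivity analysis. Boundary
inclusivity is: High at TMB ≥ high cutoff, Low at TMB < low cutoff,
Moderate in between. With published cutoffs (13.7, 2.2) this makes
exactly 13.7 High and exactly 2.2 Moderate. Note the rule is
*data-adaptive*: the package never hard-codes published cutoff values,
which arise from (and only from) the cohort it is run on. In the
degenerate all-equal cohort the SD is 0, both cutoffs coincide with the
common value, and every patient classifies High by the boundary rule.

## PD-L1 scoring

Two independent ladders over staining percentages, with inclusive lower
bounds:

* TC (percent of tumor cells expressing PD-L1): TC3 ≥ 50, TC2 in
  [5, 50), TC1 in [1, 5), TC0 < 1;
* IC (percent of tumor area occupied by PD-L1⁺ immune cells): IC3 ≥ 10,
  IC2 in [5, 10), IC1 in [1, 5), IC0 < 1.

Category 0/1/2/3 maps to negative / weak / moderate / strong positive;
"any+" means category ≥ 1. TC and IC are scored and analyzed
separately — survival work downstream uses TC only, reflecting the
common finding that IC expression carries no survival signal; a
combined max(TC, IC) grade exists but is off by default. Cytoplasmic
(non-membranous) staining has no scoring rule and is outside the data
model.

Frequency tables round percentages **half-up to integer percent**
(`round_half_up()`), the convention that reproduces published clinical
tables (e.g. 50/136 → 37%, 23/51 → 45%); exact proportions and raw
counts are always returned alongside, and the four-category table
collapses exactly onto the two-category one.

## Combined stratification

Dichotomized TMB (High vs Low/Moderate) × PD-L1 TC positivity yields
four classes: `LM_neg`, `LM_pos`, `H_pos`, `H_neg`. Survival figures in
this literature conventionally show only the first three; `H_neg`
patients exist, so the pipeline assigns and reports the class
explicitly and `run_full_analysis(exclude_h_neg = TRUE)` (the default)
merely drops it from the combined-class survival *comparison*. Overlap
(Venn) summaries report the four mutually exclusive cells under **two
normalizations** — the subgroup size and the full cohort size — because
published overlap percentages are ambiguous about their denominator.

## Survival and association statistics

* **Kaplan-Meier**: product-limit estimate via the survival package with
  Greenwood-variance log-log 95% CIs (bounded in [0, 1]). The median is
  the smallest time with S(t) ≤ 0.5; "not reached" is reported as `NA`.
  The median CI is the set of times where the pointwise CI still
  contains 0.5.
* **Log-rank**: Mantel-Haenszel chi-square on k−1 df with the standard
  hypergeometric variance under ties, two-sided.
* **Contingency tests**: Pearson chi-square, switching to Fisher's exact
  test when any expected cell count is below 5 (the conventional rule;
  the switch rule itself is rarely stated in clinical reports, so it is
  recorded in the output). The 2×2 chi-square is uncorrected by default:
  published subgroup p-values of the kind this pipeline reproduces
  (e.g. a sex-by-positivity table giving p < 0.001) only obtain without
  the Yates correction, and `correct = TRUE` is exposed.
* **Spearman** rank correlation with midranks, two-sided.
* **Kruskal-Wallis** with tie correction; **Dunn's** pairwise z tests on
  pooled midranks. Pairwise p-values are *unadjusted by default*, since
  the single pairwise P values this mirrors are reported without a named
  correction; any `p.adjust` method is available by flag.
* All tests are two-sided at α = 0.05.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions of a 187-patient
two-histology cohort; its defaults *are* those conditions and are not
tuning knobs:

| parameter | default | why |
|---|---|---|
| n_patients | 187 (73% ADC) | published cohort size and histology mix |
| panel | 200 intervals, 1.4 Mb | footprint of a ~1000-gene capture panel |
| true TMB | lognormal, meanlog log 8, sdlog 0.8 | median 8 mut/Mb; an n≈187 maximum near the reported 0–58.5 range |
| depths | 300× tumor / 200× normal, NB size 20 | modern hybrid-capture depths |
| somatic fraction | 0.5 | half of candidates truly somatic |
| strand-bias artifact rate | 0.05 | small artifact load |
| popdb leakage | 0.05 | germline escaping the database filter |
| PD-L1 mixtures | published four-category frequencies per histology | e.g. ADC TC 63/10/7/20% |
| covariates | published marginals (age 58/60, male 63%/78%, …) | cosmetic realism |
| hazards | exponential; class medians 32 / 8.5 / 6 / 12 months | see below |
| censor rate | 0.2 | administrative censoring |

Survival times are **exponential per combined class** — the simplest
model that reproduces reported class medians (median = ln 2 / λ) and
log-rank separations; reported results of this kind give only medians
and log-rank p-values, which exponential hazards fully determine. The
class medians follow the published responder/non-responder pattern
(32 months for `LM_neg`, 8.5 for `LM_pos`, 6 for `H_pos`); `H_neg` is
never plotted in that literature, so its median (12 months) is an
intermediate choice of this package. A censored patient's recorded time
is drawn uniformly within their survival time, emulating administrative
censoring during follow-up.

Candidate variants arrive as two Poisson streams: somatic coding events
at rate true-TMB × territory (plus a 15% non-coding somatic load), and
germline events at rate somatic × (1−f)/f for somatic fraction f. The
boundaries are handled explicitly — f = 0 keeps the candidate load but
labels everything germline, f = 1 emits no germline — so degenerate
configurations remain testable. Germline variants get matched
tumor/normal allele fractions (het ≈ 0.5 or hom ≈ 1) and database
counts ≥ 2 except for the leakage fraction; somatic variants get a
Beta(4, 8) tumor allele fraction and near-zero normal background.
Ground truth (per-variant label, per-patient true TMB, true combined
class from true-TMB cutoffs and TC ≥ 1%) is retained for recovery
tests.

What the generator does **not** emulate — and hence what green tests do
not show about real data: read-level errors and mapping artifacts
(evidence is simulated at the count level), locus-specific coverage
bias (GC content, target footprint, repeats), correlation between
biomarkers and covariates (smoking, stage and sex are drawn
independently of TMB and PD-L1), intratumor heterogeneity, and
non-exponential survival shapes. Recovery results therefore validate
the *machinery*, not clinical effect sizes.

## Numerical choices and degenerate inputs

* Child seeds for internal streams are derived from the user seed and
  kept below 2³¹; identical config + seed gives byte-identical files
  (tested on the full cohort export and the report bundle).
* Panel simulation distributes exactly `round(territory × 10⁶)` bases
  over intervals via largest-remainder rounding, so territory is
  conserved to the base.
* Zero-depth samples are uncallable: `somatic_p()` errors, and inside
  the chain the variant fails the somatic-test rule.
* Zero alt reads make strand bias undefined: error standalone,
  configurable fail/pass in the chain.
* Cohorts of fewer than 2 TMB values have no SD and are rejected;
  empty groups are rejected by every test; all-censored groups report a
  not-reached median rather than a number.
* Rare positional collisions in the simulator are deduplicated so each
  (patient, chrom, pos, ref, alt) key is unique, which the cohort
  filter enforces on input.

## Problem sizes used by the test suite

The suite exercises: oracle equivalence of the filter chain against an
independently coded brute-force evaluator on 500 random ≤20-variant
instances; KM median recovery on n = 1000 exponential draws (32-month
closed form, ±2 months); log-rank size on 2000 null replicates (within
[0.03, 0.07] at α = 0.05); end-to-end recovery of planted 1:2:4 class
hazards at n = 300 with a 200-replicate power check (≥ 90% rejection);
and TMB parameter recovery (mean absolute relative error < 10% at
n = 200 patients, ≥ 100× depth). These sizes were chosen as the
smallest at which the corresponding sampling error is comfortably below
the tolerance being asserted.

## Known limitations

* Annotation values (database counts, deleteriousness scores, zygosity
  calls) are consumed, never computed; disagreement between real
  annotators is out of scope.
* No Cox regression or multivariable adjustment is provided — the
  analyses mirrored here are univariate by design.
* The depth-bias corrections some pipelines apply (GC, footprint,
  repeats) are unspecified in this setting and not implemented.
* The printed-percentage reproduction depends on half-up rounding; a
  cohort whose proportions sit exactly on .5 boundaries will differ
  from banker's-rounding outputs by one percentage point.
```{r session}
sessionInfo()
```
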