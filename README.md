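# igmnet

Neural-net subgroup discovery linking immunoglobulin M (IgM) to
psychopathology in naturalistic polypharmacy cohorts.

## The problem

In cohorts of hospitalized patients with depressive (ICD-10 F3) or
schizophrenic (F2) disorders, serum IgM — a "natural" antibody whose
chronic elevation marks an aberrant inflammatory response system — shows
no sample-wide association with psychopathology. The working hypothesis
is that such an association exists only in an initially unknown subgroup
of patients (roughly a fifth to a quarter of each diagnosis class).
igmnet implements the full analysis chain needed to study that
hypothesis quantitatively, for methodologists and biostatisticians who
want a tested, seeded, fully synthetic-data-backed reference
implementation:

* **Instrument scoring and classification rules** for HAM-D17/21,
  PANSS, the MEDIS side-effect inventory and lifetime syndrome check
  lists: severity strata, the DL×SL diagnostic overlap zone (strict
  thresholds `SL>35 & DL>30` for F2, `SL>25 & DL>35` for F3),
  responder / partial / non-responder categories from endpoint percent
  reduction (≥50% HAM-D17 for F3, ≥40% PANSS-P for F2, partial ≥20%),
  and side-effect bins on the global score S.
* **Pairwise syndrome-profile concordance**: all n(n−1)/2 comparisons of
  range-normalized syndrome profiles, `1 − mean|Δ|`.
* **A sigmoid backpropagation network from first principles** (online
  updates `Δw_ij = α·ε_i·s_j·s_i(1−s_i)`,
  `Δw_jk = α·Σ_i ε_i·s_k·s_i(1−s_i)·w_ij·s_j(1−s_j)`), gradient-checked
  against finite differences, with a 10-fold cross-validation harness.
* **The constrained subgroup search**: the largest patient subgroup with
  a significant positive IgM–global-score correlation and a bounded
  false-positive response-prediction rate, with membership assigned
  through 10-fold cross-validated network predictions; plus a simple
  IgM-cutoff baseline it is measured against.
* **Variance decompositions**: per-cluster side-effect variance
  explained by the drug count (OLS), and polypharmacy determinants
  (linear additive vs ward-only vs cross-validated network).
* **A seeded synthetic cohort generator** (195 F3 + 84 F2 patients, 8
  visits at days 0/3/7/10/14/21/28/35, planted IgM-linked subtype,
  ward-driven polypharmacy, drug-count-driven side effects) so that
  every stage is testable without any clinical data.

## Worked example

```r
library(igmnet)

coh <- generate_cohort(generator_config(seed = 1))
coh
#> Synthetic cohort: 279 patients (195 F3, 84 F2), 2123 assessments
#>   seed 1, planted subgroup members: 57

cohort_summary(coh)[, c("diagnosis", "n", "baseline_mean",
                        "drug_count_mean", "polypharmacy_pct")]
#>   diagnosis   n baseline_mean drug_count_mean polypharmacy_pct
#> 1        F3 195          23.9            3.29             76.4
#> 2        F2  84          36.1            3.49             86.9
```

Baselines sit at the study means (HAM-D17 23.9 vs 23.1 ± 5.7; PANSS-G
36.1 vs 35.8 ± 8.8), drug counts at 3.2/3.5 per patient, and three
quarters of patients and more are under polypharmacy (≥2 drugs).

```r
cm <- pairwise_concordance(generate_cohort(
  generator_preset("f2_concordance", seed = 1)))
cm
#> Pairwise syndrome-profile concordance: 100 patients, 4950 pairs
#>   mean 0.549, sd 0.196
```

4950 = 100·99/2 comparisons; the mean key-syndrome concordance of ~0.54
reproduces the ~0.536 reported for between-patient comparisons in
schizophrenic disorders.

```r
coh2 <- generate_cohort(generator_preset("study_f2", seed = 1))
smp  <- exclude_incomplete(coh2, "F2")
mod  <- subgroup_search(smp, seed = 1)
mod
#> NN subgroup model (F2): 14/80 members (17.5%), r = 0.874 (p = 4.3e-05),
#>   FP 7.1%, 76.4% variance
```

On an 80-patient F2 sample with a planted 22.5% subgroup (population
r = 0.8), the search returns a 17.5% subgroup whose IgM–score
correlation is 0.874 (p < 1e-4) with a 7.1% false-positive
response-prediction rate — the same report shape as the study's
22.5%/r = 0.746/FP 5.6% headline model.

```r
head(drug_side_effect_analysis(coh)[, 1:3], 4)
#>            cluster variance_explained_pct     slope
#> 1            sleep                   13.7 0.5378158
#> 2         appetite                   14.9 0.5147567
#> 3        sexuality                   12.9 0.5455736
#> 4 gastrointestinal                   10.4 0.4384731
```

The number of drugs alone explains 10–15% of the variance in each
side-effect cluster — the order of magnitude (11.8–18.4%) reported for
real data.

A full run (`run_pipeline(generator_config(seed = 1), "out/")`) writes
the cohort tables, summary, concordance pair list, per-diagnosis
discovery reports and variance analyses with a manifest recording seed
and configuration hash; `inst/cli/igmnet` exposes the subcommands
`simulate`, `score`, `concordance`, `discover`, `variance`, `run-all`.

## Repository layout

* `R/`, `src/` — implementation (R plus one compiled training loop).
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (finite differences, exhaustive enumeration,
  normal equations, `cor.test`).
* `vignettes/igmnet-methods.Rmd` — models, assumptions, tunable
  parameters, numerical choices and known limitations.
* `inst/extdata/data_dictionary.csv` — column-level documentation of
  the cohort files.
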