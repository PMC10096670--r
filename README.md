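# prsgxe

Does an unhealthy diet or lifestyle modify the genetic susceptibility to
impulsivity? `prsgxe` re-implements, as a tested R package plus a scripted
analysis workflow, a staged gene–environment interaction (GxE) analysis of
ADHD polygenic risk and diet/lifestyle behaviours on trait impulsivity in a
large adult population cohort. It is aimed at researchers in genetic
epidemiology who want to reproduce, stress-test or extend this class of
polygenic-score-by-environment analysis without access to the underlying
(application-only) cohort data.

## What it computes

- **Outcome** — an impulsivity score: the first principal component of four
  NEO facet sum scores (impulsivity, excitement-seeking, and inverted
  deliberateness and self-discipline), standardized.
- **Predictor** — an aggregated ADHD polygenic risk score (PRS):
  summary-statistic QC (multiallelic and strand-ambiguous removal,
  MAF > 0.01, INFO > 0.8) → greedy LD clumping (r² < 0.1, ±250 kb) →
  scoring at 11 p-value thresholds, score_i = Σ_j β_j · dosage_ij for
  p_j ≤ t → **PRS-PCA**: the first principal component of the standardized
  11-score panel, so no threshold needs to be chosen.
- **Moderators** — four diet indices (diet-quality score over 12 food-group
  quintiles, and energy/fat/free-sugar excess ratios censored at 1, with
  Schofield-BMR reliability filtering and tertile/binary grouping) and four
  lifestyle variables (MVPA quintile score, sleep residual-decile classes,
  alcohol bands, smoking status).
- **Models** — step 1: OLS of impulsivity on PRS + covariates + genetic
  controls; steps 2a/2b: one model per moderator adding its main effects
  and PRS×moderator products, flagged at the Bonferroni level 0.0125; a
  two-step residual procedure for the % variance explained by the PRS; and
  SES-interaction sensitivity models plus PRS–exposure correlations (rGE).
- **Synthetic cohort** — a seeded generator (LD-block genotypes via a
  calibrated Gaussian copula, noisy GWAS summary statistics, exposures
  calibrated to the published cohort descriptives, outcome built from the
  derived variables with known coefficients, optional rGE dial) that makes
  every published effect size a recoverable ground truth.

## Worked example

```r
library(prsgxe)

cfg <- simulation_config(n_samples = 20000, n_variants = 400, n_blocks = 40,
                         outcome_coefficients = generating_coefficients("kcal"),
                         seed = 20260930)
sc  <- simulate_cohort(cfg)
d   <- sc$cohort[sc$cohort$energy_reliable, ]

fit <- fit_step2(d, "kcal")          # energy-intake interaction model
fit$terms[grepl("prs|kcal", fit$terms$term), c("term", "B", "p")]
```

```
               term          B            p
                prs 0.01906387 1.036547e-01
     kcal_tertileQ2 0.05866488 4.135000e-04
     kcal_tertileQ3 0.14103546 2.112159e-17
 prs:kcal_tertileQ2 0.02451502 1.407232e-01
 prs:kcal_tertileQ3 0.01662311 3.152042e-01
```

The cohort was generated with a PRS main effect of 0.008 in the lowest
energy tertile, tertile main effects 0.058/0.128 and PRS×tertile
interactions 0.032/0.038: the tertile main effects are recovered and
clearly significant, while this single n = 20,000 draw estimates the Q3
interaction at 0.017 with a 95% CI that covers the generating 0.038 —
individual draws are noisy, which is exactly why the recovery studies below
average 50 replicates at the full n = 33,047. On the same cohort,

```r
two_step_r2(d)$variance_explained_pct   # 0.106 (% of variance, this draw)
```

The full workflow — simulate, build the PRS from summary statistics, derive
the variables from raw ingredients, fit the nine-model battery, run the
sensitivity analyses — is scripted:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_polygenic_score.R
Rscript analysis/03_derive_variables.R
Rscript analysis/04_interaction_models.R
Rscript analysis/05_sensitivity.R
```

Each step prints what it found and writes tables under `results/`.

## Package layout

- `R/` — simulation (`simulate_*`), genetics (`qc_summary_stats`,
  `ld_clump`, `score_prs`, `prs_pca`, `rge_correlations`), derived
  variables (`impulsivity_pc`, `schofield_bmr`, `excess_ratios`, `llds`,
  classifications), models (`fit_linear`, `fit_step2`, `two_step_r2`,
  `sensitivity_ses`), IO and the `run_pipeline()` orchestrator.
- `analysis/` — the numbered workflow drivers.
- `vignettes/gxe-methods.Rmd` — the model, its assumptions, calibration
  choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force oracles for clumping and the principal-component projection.
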