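---
title: "Methods: polygenic risk, diet and lifestyle interaction on impulsivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, diet and lifestyle interaction on impulsivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsgxe)
```

## The scientific question

Trait impulsivity in adults is partly heritable and partly shaped by
behaviour. This package implements a staged analysis asking whether an
unhealthy diet (poor overall diet quality, excess energy, fat or free-sugar
intake) or other lifestyle behaviours (sleep duration, smoking, alcohol,
physical activity) *modify* the association between polygenic risk for ADHD
and trait impulsivity — a gene–environment (GxE) interaction in the
diathesis–stress sense — in a large adult population cohort.

Because the individual-level cohort data are access-controlled, the package
pairs the analysis code with a seeded synthetic-cohort generator whose
statistical structure matches what the analysis assumes. Every stage is
therefore testable end to end, and the generating coefficients are known
exactly, which turns the published effect sizes into recoverable ground
truth for simulation studies.

## The outcome: an impulsivity principal component

Four NEO personality facets are measured as sum scores of eight 1–5 Likert
items each (range 8–40): impulsivity, excitement-seeking, deliberateness
and self-discipline. `impulsivity_pc()` inverts deliberateness and
self-discipline as $48 - \text{sum}$ (which maps $[8,40]$ onto itself, so
higher always means more impulsive), computes the $4\times4$ Pearson
correlation matrix, and takes the first principal component, oriented so
the impulsivity facet loads positively and standardized to mean 0, sd 1.
Because the component is correlation-based it is invariant to adding a
constant to any facet. The estimation sample may be supplied separately
from the scored sample (the original analysis estimated loadings on a
larger superset of the genotyped sample).

## The predictor: an aggregated polygenic score

The polygenic score pipeline follows standard clumping-and-thresholding
practice with a principal-component aggregation:

1. **QC** (`qc_summary_stats()`): duplicated variant ids (multiallelic
   stand-ins) are removed entirely, as are strand-ambiguous A/T and C/G
   variants, variants with MAF ≤ 0.01 or INFO ≤ 0.8, and variants absent
   from the target panel.
2. **Clumping** (`ld_clump()`): greedy selection of the most significant
   variant, removing neighbours within ±250 kb with $r^2 \ge 0.1$
   (dosage correlation in the reference panel, pairwise-complete). Ties in
   p are broken toward the smaller genomic position so the result is
   deterministic. The survivor condition is printed as $r^2 < 0.1$, so the
   removal comparison uses $\ge$.
3. **Scoring** (`score_prs()`): at each of 11 p-value thresholds
   ($5\times10^{-8}$ … 1), the score is the weight (log odds ratio) times
   the counted-allele dosage summed over qualifying variants. Alleles are
   harmonized by exact pair matching; a swapped pair flips the dosage to
   $2-d$; anything else is an error (strand flips cannot arise because
   ambiguous variants were removed). Missing dosages are mean-imputed per
   variant, matching common scoring practice. Columns are z-standardized;
   zero-variance columns are flagged and excluded from the PCA.
4. **PRS-PCA** (`prs_pca()`): the final score is the first principal
   component of the standardized multi-threshold panel, which avoids
   optimizing the threshold as a free parameter. The component is oriented
   so the mean loading is positive and re-standardized. One consequence of
   this convention is worth stating: reversing the sign of *every* column
   mirrors the component (the convention re-orients with the panel), while
   flipping a subset of columns leaves the score unchanged; the test suite
   asserts both behaviours.

Variance explained is estimated by a two-step residual procedure
(`two_step_r2()`): impulsivity is residualized on age, sex, genotyping chip,
four genetic PCs and chip×PC products, and the residuals are regressed on
the score; the adjusted $R^2$ of the second model (×100) is reported, and
can be slightly negative under the null.

## Derived diet and lifestyle variables

- **Schofield BMR** (`schofield_bmr()`): sex- and age-band (18–30, 30–60,
  60+) linear equations in weight (kg) and height (m). The weight-and-height
  variant is used; which variant the original cohort pipeline used is not
  recorded, but weight is recoverable from BMI and height, and the variant
  choice moves BMR by far less than the width of the reliability band.
- **Reliability filter** (`energy_reliability()`): records reporting less
  than 0.79 or more than 2.49 times BMR are excluded; the boundaries
  themselves are retained because the printed exclusion rule is strict.
- **Excess ratios** (`excess_ratios()`): KCAL = energy/BMR, FAT = fat% / 30,
  SUGAR = sugar% / 10 (WHO maxima). Values below 1 are censored to 1:
  below-maximum intake is not placed on a continuum with excess.
- **Diet-quality score** (`llds()`): 12 food groups in g/1000 kcal, scored
  0–4 by within-sample quintile (reversed for red/processed meat,
  butter/hard margarines and sugar-sweetened beverages), summed to 0–48.
  The inverted score is defined as `llds_i = 48 - llds`, which preserves the
  printed range; the source describes only "inverting" the score, so the
  complement is a design choice recorded here. Quintiles use average ranks
  with boundary values to the lower bin, so scoring is deterministic and
  order-independent, and a fully tied group scores 2 for everyone.
- **Grouping** (`tertile_groups()`, `binary_sugar()`): empirical tertiles
  with order-statistic cut-points (classes even to within one person on
  distinct data; boundary values to the lower tertile, matching the printed
  half-open ranges). Sugar is binary (ratio exactly 1 vs above) because more
  than a third of participants report non-excessive intake — a tertile split
  would put a mass point across a cut.
- **Physical activity** (`mvpa_quintile()`): fixed bands at 60/150/255/420
  min/week. The printed bands "150–255" and "250–420" overlap; 255 is
  adopted as the single boundary on the assumption of a single-digit typo,
  giving contiguous bands.
- **Sleep** (`sleep_class()`): lowest/highest decile of residuals from a
  regression of sleep hours on age and sex; by construction 10%/80%/10% of
  any sample. Degenerate designs (constant age, single-sex samples) drop
  the constant term rather than failing.
- **Alcohol** (`alcohol_class()`): the printed band labels ("15–29.9",
  ">30") leave small gaps; contiguous half-open bins
  $[2.5, 15)$, $[15, 30)$, $[30, \infty)$ are used, so 30.0 g/day is
  "heavy". Only reported zero intake is "abstinent".
- **Smoking** (`smoking_class()`): current (past month) takes precedence
  over past (ever ≥ 1 year), else never.

## The regression battery

All models are ordinary least squares on complete cases, with 95% CIs from
the t distribution (no robust errors — nothing in the source analysis
indicates them). **Step 1** regresses impulsivity on the polygenic score
plus covariates (age, sex, BMI, four SES indices, non-communicable disease,
depression, anxiety, stressful life events, long-term difficulties) and the
genetic controls (chip, four genetic PCs, chip×PC). **Step 2a** adds one
diet indicator and its score interaction per model (four models); **step
2b** does the same for the lifestyle predictors. Reference levels are the
lowest tertile, Q1, normal sleep, never-smoker and abstinent; the activity
score enters as a single semi-continuous term. Significance is flagged at
the Bonferroni level $0.05/4 = 0.0125$, applied within each step.

The "Beta" column reports $B \cdot sd(x)/sd(y)$ computed on the analysis
sample, including for dummy columns. How the original analysis standardized
its betas is not stated; this definition reproduces the scale pattern of
the published tables and is the common default.

**Sensitivity** (`sensitivity_ses()`): the step-2 model is augmented with
moderator×SES products for all four SES indices; the change in the
score-by-moderator coefficient measures how much confounder-by-exposure
interactions inflated the GxE estimate. `rge_correlations()` reports
Pearson correlations between the score and each exposure as a measure of
gene–environment correlation (rGE).

A deliberately simple median/mode imputer (`simple_impute()`) is provided
as plumbing for incomplete covariates; chained-equation imputation is out
of scope, synthetic cohorts are complete, and complete-case analysis is the
default.

## The synthetic cohort generator

`simulate_cohort()` produces genotypes, GWAS summary statistics and a
phenotype table with known generating truth.

**Genotypes.** MAFs are uniform on [0.05, 0.5]. Within each LD block a
latent Gaussian with exchangeable correlation is mapped through the
binomial(2, MAF) quantile function to dosages — a Gaussian copula with
valid allele-frequency margins. The discreteness of the margins attenuates
correlation, so the latent correlation is inflated through a frozen
Monte-Carlo calibration curve to make the realized mean dosage correlation
match `block_r`; binomial margins cap attainable correlation near 0.77, so
`block_r` is restricted to [0, 0.75]. Blocks sit on chromosomes 1–22 with
2 Mb gaps (independent for clumping purposes); variants are 5 kb apart.
Chips are assigned 80/20, mirroring the two genotyping arrays of the
original cohort; genetic PCs are independent standard normals.

**Summary statistics.** A `causal_fraction` of variants receives true
effects $\sim N(0, \text{effect\_sd}^2)$; observed effects add noise with
variance $1/(N \cdot 2p(1-p))$ for discovery size $N$ (default 225,534, the
ADHD meta-GWAS scale). A small fraction of non-causal variants is emitted
strand-ambiguous, and a few ids are duplicated, so QC always has work to do.

**Phenotypes.** Covariates use simple parametric forms calibrated to the
published cohort descriptives: age truncated-normal (42.1, 12.35) on
[18, 90]; 59.8% female; BMI normal (25.51, 4.04); negative-binomial stress
counts whose dispersions are chosen so the implied standardized effects
match the published table (e.g. long-term difficulties has sd ≈ 2.36);
education 25.5/40.8/33.7%. The energy, fat and sugar ratios are lognormal
with medians 1.28/1.18/1.06 and log-sds 0.24/0.125/0.45 — chosen so the
resulting tertile cut-points land at the printed boundaries (≈1.14/1.41 for
energy, ≈1.12/1.25 for fat) and so ~45% of sugar ratios censor to 1 (the
printed grouping requires > 33%). Food-group intakes are lognormal around
plausible g/1000 kcal medians with a weak common diet-quality factor
(pairwise latent correlation 0.05) so the diet-score spread approaches the
published sd ≈ 6 rather than the independence value 4.9. The empirical
shapes of real food-frequency data are *not* reproduced — only these
summary calibrations are; passing tests therefore show correctness of the
derivation and modelling code, not realism of any particular food group.

**Outcome.** The impulsivity score is a linear combination of the *derived*
variables (score, tertile dummies, lifestyle classes, covariates) with the
coefficients of `generating_coefficients()`, plus Gaussian noise whose sd
is calibrated (empirically, per draw) so the outcome variance is 1. Raw
ingredients are drawn first and the derivation functions themselves produce
the columns the outcome is built from, so generating coefficients are
exactly recoverable by the fitting code while the derivation code is
exercised end to end. NEO facet sums are back-filled from the outcome with
correlations 0.81/0.37/0.82/0.68 — chosen to reproduce the published
loading pattern qualitatively — then rounded and clamped to [8, 40], so the
facet-derived component correlates ≈ 0.9 with the generated outcome but is
not identical to it; recovery simulations fit the generated outcome
directly.

**rGE dial.** With `rge_gamma` $= \gamma$, the latent log-scales of the
four diet exposures mix in a $\gamma$-weighted score component
($\sqrt{1-\gamma^2}\,Z + \gamma\,\text{PRS}$, oriented so higher risk means
worse diet). Censoring attenuates the realized Pearson correlation slightly
(≈ 8% for the energy ratio), so $\gamma = 0.05$ yields $r \approx 0.046$ —
inside the 0.03–0.07 acceptance band used in the tests. Correlation is
monotone in $\gamma$.

**Seeding.** All randomness flows from one root seed through
`derive_seed(seed, stream)` — a fixed affine congruence modulo $2^{31}-1$ —
with one stream per stage (genotypes, summary statistics, phenotypes) and
per simulation replicate, so identical configurations are bit-identical and
sub-studies are independent.

## Problem sizes and numerical choices

The recovery simulation studies use 50 replicates of cohorts of n = 33,047
(the published analysis sample size) with a 120-variant, 12-block panel —
the score enters the outcome standardized, so panel size does not affect
coefficient recovery, only the realism of the scoring stage, which has its
own tests. Monte-Carlo standard errors at these settings are ≈ 0.0017 for
the energy-interaction coefficient, ≈ 0.0007 for the score main effect and
≈ 0.01 percentage points for the variance-explained study. Coverage and
type-I-error properties are checked at n = 2,000 over 500 replicates.
Degenerate inputs are handled explicitly: empty thresholds are flagged and
excluded from the PCA, constant facets and rank-deficient designs raise
errors naming the offending columns, and decile/tertile rules demand
minimum sample sizes rather than returning silently wrong groups.

## Known limitations

- LD structure is exchangeable within synthetic blocks; real human LD maps,
  Hardy-Weinberg testing and imputation-quality variation are not modelled.
- The generator emulates summary statistics of a case-control GWAS at the
  level of effect-size noise only; no case-control sampling is simulated.
- Shrinkage-based scoring (LDpred-style), cross-ancestry portability and
  chained-equation imputation are out of scope.
- Family relatedness is not modelled; all regressions assume independent
  observations, as did the source analysis.
- The facet back-fill reproduces the published loading *ordering*, not the
  exact loadings; the impulsivity component of real data would differ.
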