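# Synthetic cohort generator: seeded GWAS summary statistics, LD-block
# genotype dosages, diet/lifestyle exposures, covariates and an impulsivity
# outcome with known generating coefficients.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults encode the
#' study conditions the analysis assumes: a discovery GWAS of roughly 225,000
#' subjects, a polygenic architecture with a minority of causal variants, and
#' an outcome model whose coefficients default to the basic
#' polygenic-score-plus-covariates set (see [generating_coefficients()]),
#' with the residual standard deviation calibrated so that the outcome
#' variance is approximately 1.
#'
#' @param n_samples Number of cohort members.
#' @param n_variants Number of variants.
#' @param n_blocks Number of LD blocks (must not exceed `n_variants`).
#' @param block_r Target mean within-block dosage correlation, in \[0, 0.75\].
#'   Dosages have binomial(2, MAF) margins, which bound the attainable
#'   pairwise correlation; the generator inflates the latent Gaussian
#'   correlation through a fixed calibration curve so the realized dosage
#'   correlation matches `block_r` on average.
#' @param causal_fraction Fraction of variants with nonzero true effects.
#' @param effect_sd Standard deviation of true log-odds effects.
#' @param gwas_n Effective discovery sample size; summary-statistic noise has
#'   variance 1 / (gwas_n * 2 * MAF * (1 - MAF)). `Inf` gives noise-free
#'   summary statistics.
#' @param ambiguous_fraction Fraction of (non-causal) variants emitted with
#'   strand-ambiguous alleles (A/T or C/G) to exercise quality control.
#' @param duplicate_n Number of duplicated variant ids emitted as
#'   multiallelic stand-ins.
#' @param outcome_coefficients Named vector of generating coefficients; names
#'   must be terms the generator knows (see [generating_coefficients()]).
#' @param residual_sd Residual standard deviation of the outcome; `NULL`
#'   (default) calibrates it so the outcome variance is 1.
#' @param rge_gamma Gene-environment correlation dial in (-1, 1): the latent
#'   scales of the four diet exposures receive a `rge_gamma`-weighted
#'   polygenic-score component (worse diet for higher scores). 0 disables it.
#' @param seed Root seed; all stage seeds are derived from it via
#'   [derive_seed()].
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 2000, n_variants = 120,
                              n_blocks = 12, block_r = 0.3,
                              causal_fraction = 0.3, effect_sd = 0.05,
                              gwas_n = 225534, ambiguous_fraction = 0.02,
                              duplicate_n = 2,
                              outcome_coefficients = generating_coefficients("basic"),
                              residual_sd = NULL, rge_gamma = 0, seed = 1) {
  stopifnot(n_samples >= 1, n_variants >= 1, n_blocks >= 1,
            causal_fraction >= 0, causal_fraction <= 1,
            effect_sd >= 0, gwas_n > 0,
            ambiguous_fraction >= 0, ambiguous_fraction < 1,
            duplicate_n >= 0, abs(rge_gamma) < 1)
  if (n_blocks > n_variants)
    stop("configuration error: n_blocks (", n_blocks,
         ") exceeds n_variants (", n_variants, ")")
  if (block_r < 0 || block_r > 0.75)
    stop("configuration error: block_r must lie in [0, 0.75]; ",
         "binomial dosage margins cap the attainable correlation")
  if (!is.null(residual_sd) && residual_sd <= 0)
    stop("configuration error: residual_sd must be positive")
  if (is.null(names(outcome_coefficients)) ||
      any(!nzchar(names(outcome_coefficients))))
    stop("configuration error: outcome_coefficients must be a named vector")
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 n_blocks = as.integer(n_blocks),
                 block_r = block_r, causal_fraction = causal_fraction,
                 effect_sd = effect_sd, gwas_n = gwas_n,
                 ambiguous_fraction = ambiguous_fraction,
                 duplicate_n = as.integer(duplicate_n),
                 outcome_coefficients = outcome_coefficients,
                 residual_sd = residual_sd, rge_gamma = rge_gamma,
                 seed = seed),
            class = "sim_config")
}

# Frozen Monte-Carlo calibration of the latent Gaussian correlation needed to
# realize a given mean dosage correlation when MAF ~ U(0.05, 0.5).
.copula_calibration <- data.frame(
  latent = c(0, .1, .2, .3, .4, .5, .6, .7, .8, .9, .95, .99),
  dosage = c(0, 0.070368, 0.142012, 0.214857, 0.289824, 0.366142,
             0.444256, 0.524172, 0.606430, 0.691357, 0.734742, 0.769862)
)

.latent_block_r <- function(block_r) {
  if (block_r <= 0) return(0)
  stats::approx(.copula_calibration$dosage, .copula_calibration$latent,
                xout = block_r, rule = 2)$y
}

#' Simulate LD-block genotype dosages
#'
#' Draws per-variant minor allele frequencies uniform on \[0.05, 0.5\] and
#' dosages from a Gaussian copula: within each block the latent normals share
#' an exchangeable correlation, and each latent value is mapped to a dosage
#' in \{0, 1, 2\} through the binomial(2, MAF) quantile function. Blocks are
#' placed on chromosomes 1-22 with 2 Mb gaps so they are independent for
#' clumping purposes; variants within a block sit 5 kb apart. Each sample is
#' assigned one of two genotyping chip labels (80/20) and four independent
#' standard-normal genetic principal components.
#'
#' @param config A [simulation_config()].
#' @return An object of class `genotype_data`: a list with `dosages`
#'   (n x m matrix, dimnames sample/variant ids), `variants` (data frame:
#'   `id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `maf`, `info`)
#'   and `samples` (data frame: `sample_id`, `chip`, `pc1`-`pc4`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples
  m <- config$n_variants
  block <- sort(rep_len(seq_len(config$n_blocks), m))
  maf <- stats::runif(m, 0.05, 0.5)
  rl <- .latent_block_r(config$block_r)

  D <- matrix(0L, n, m)
  for (b in seq_len(config$n_blocks)) {
    idx <- which(block == b)
    k <- length(idx)
    Z <- matrix(stats::rnorm(n * k), n, k)
    if (rl > 0) Z <- sqrt(1 - rl) * Z + sqrt(rl) * stats::rnorm(n)
    for (j in seq_along(idx)) {
      D[, idx[j]] <- stats::qbinom(stats::pnorm(Z[, j]), 2, maf[idx[j]])
    }
  }

  # Non-ambiguous allele pairs only; strand-ambiguous variants are injected
  # later at the summary-statistics stage.
  pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                 c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  pick <- sample.int(nrow(pairs), m, replace = TRUE)

  chrom <- ((block - 1L) %% 22L) + 1L
  pos <- integer(m)
  for (ch in unique(chrom)) {
    bl_here <- unique(block[chrom == ch])
    for (i in seq_along(bl_here)) {
      idx <- which(block == bl_here[i])
      pos[idx] <- (i - 1L) * 2000000L + 10000L + seq_along(idx) * 5000L
    }
  }

  ids <- sprintf("rs%06d", seq_len(m))
  sample_ids <- sprintf("S%05d", seq_len(n))
  dimnames(D) <- list(sample_ids, ids)

  variants <- data.frame(
    id = ids, chrom = as.character(chrom), pos = pos,
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    maf = maf, info = 1.0, stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sample_ids,
    chip = sample(c("chipA", "chipB"), n, replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("pc", 1:4)))
  samples <- cbind(samples, as.data.frame(pcs))

  structure(list(dosages = D, variants = variants, samples = samples),
            class = "genotype_data")
}

#' Simulate GWAS summary statistics for the simulated panel
#'
#' A fixed fraction of variants receives true log-odds effects drawn from
#' N(0, `effect_sd`^2); the rest are null. Observed effects add sampling
#' noise with variance 1 / (`gwas_n` * 2 * MAF * (1 - MAF)); two-sided
#' p-values come from the implied z statistic. A small fraction of non-causal
#' variants is emitted with strand-ambiguous alleles and a few ids are
#' duplicated (multiallelic stand-ins), so downstream quality control has
#' something to remove. The true effects are attached as attribute
#' `"truth"`.
#'
#' @param genotypes A `genotype_data` object.
#' @param config The [simulation_config()] used to create it.
#' @return A `summary_stats` data frame with columns `snp`, `chr`, `pos`,
#'   `a1` (effect allele), `a2`, `beta`, `p`, `freq`, `info`.
#' @export
simulate_summary_stats <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  v <- genotypes$variants
  m <- nrow(v)

  n_causal <- round(config$causal_fraction * m)
  causal <- rep(FALSE, m)
  if (n_causal > 0) causal[sample.int(m, n_causal)] <- TRUE
  beta_true <- ifelse(causal, stats::rnorm(m, 0, config$effect_sd), 0)

  se <- if (is.finite(config$gwas_n)) {
    1 / sqrt(config$gwas_n * 2 * v$maf * (1 - v$maf))
  } else rep(0, m)
  beta_obs <- beta_true + if (all(se == 0)) 0 else stats::rnorm(m, 0, se)
  z <- ifelse(se > 0, beta_obs / se,
              ifelse(beta_obs == 0, 0, Inf))
  p <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)

  a1 <- v$effect_allele
  a2 <- v$other_allele
  n_amb <- round(config$ambiguous_fraction * m)
  if (n_amb > 0) {
    cand <- which(!causal)
    amb <- cand[seq_len(min(n_amb, length(cand)))]
    flip <- c(A = "T", T = "A", C = "G", G = "C")
    a2[amb] <- unname(flip[a1[amb]])
  }

  ss <- data.frame(snp = v$id, chr = v$chrom, pos = v$pos,
                   a1 = a1, a2 = a2, beta = beta_obs, p = p,
                   freq = v$maf, info = v$info, stringsAsFactors = FALSE)

  if (config$duplicate_n > 0 && m > 1) {
    dup <- ss[sample.int(m, min(config$duplicate_n, m)), , drop = FALSE]
    dup$beta <- dup$beta + stats::rnorm(nrow(dup), 0, 0.01)
    ss <- rbind(ss, dup)
  }
  rownames(ss) <- NULL
  attr(ss, "truth") <- data.frame(id = v$id, beta_true = beta_true,
                                  stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

# Analytic variance of the truncated normal age distribution used by the
# generator (mean 42.1, sd 12.35, truncated to [18, 90]).
.age_var <- function() {
  mu <- 42.1; s <- 12.35
  a <- (18 - mu) / s; b <- (90 - mu) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
}

#' Polygenic-score coefficient for a target residualized variance share
#'
#' Returns the generating coefficient `b` for the standardized polygenic
#' score such that, when the outcome is generated from the score plus age
#' and sex effects (coefficients -0.021 and 0.036) with unit total variance,
#' the score accounts for `share` of the variance that remains after
#' residualizing on age, sex and the genetic-control block - i.e. the
#' quantity the two-step procedure of [two_step_r2()] estimates.
#'
#' @param share Target variance share as a fraction (e.g. 0.0039 for 0.39%).
#' @return The polygenic-score coefficient.
#' @export
prs_coef_for_share <- function(share) {
  stopifnot(share > 0, share < 1)
  v_agesex <- 0.021^2 * .age_var() + 0.036^2 * (0.598 * 0.402)
  sqrt(share * (1 - v_agesex))
}

.clamp_facet <- function(x) pmin(40, pmax(8, round(x)))

#' Simulate the cohort phenotype table
#'
#' Draws covariates and raw diet/lifestyle ingredients calibrated to the
#' descriptive statistics of a large adult Dutch population cohort, derives
#' the analysis variables (excess ratios, diet-quality score, tertiles,
#' lifestyle classes) by running the package's own derivation functions on
#' the raw ingredients, and generates the impulsivity outcome as the linear
#' combination `outcome_coefficients` of those derived terms plus Gaussian
#' noise. Because the outcome is built from the derived variables
#' themselves, the generating coefficients are exactly recoverable by the
#' model battery. NEO facet sums consistent with the outcome are back-filled
#' so the outcome-derivation code can be exercised end to end.
#'
#' The true polygenic score is the standardized weighted sum of dosages with
#' the true (noise-free) effects; it is stored in the cohort column `prs`.
#' If `rge_gamma` is nonzero the latent scales of the four diet exposures
#' receive an additive polygenic-score component.
#'
#' @param genotypes A `genotype_data` object (defines n and the score).
#' @param summary_stats Matching `summary_stats` (carries the true effects).
#' @param config The [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `genotypes`,
#'   `summary_stats`, `cohort` (data frame) and `truth` (generating
#'   parameters actually used).
#' @export
simulate_cohort_table <- function(genotypes, summary_stats, config) {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(config, "sim_config"))
  n <- nrow(genotypes$dosages)
  set.seed(derive_seed(config$seed, 3L))

  tr <- attr(summary_stats, "truth")
  if (is.null(tr)) stop("summary_stats lacks the truth attribute")
  bt <- tr$beta_true[match(colnames(genotypes$dosages), tr$id)]
  bt[is.na(bt)] <- 0
  g <- drop(genotypes$dosages %*% bt)
  prs <- if (stats::sd(g) > 0) as.numeric(scale(g)) else stats::rnorm(n)

  # -- covariates (parametric forms calibrated to cohort descriptives) -----
  u <- stats::runif(n, stats::pnorm(18, 42.1, 12.35),
                    stats::pnorm(90, 42.1, 12.35))
  age <- stats::qnorm(u, 42.1, 12.35)
  sex <- factor(ifelse(stats::runif(n) < 0.598, "female", "male"),
                levels = c("male", "female"))
  height <- ifelse(sex == "female", stats::rnorm(n, 1.68, 0.065),
                   stats::rnorm(n, 1.81, 0.07))
  bmi <- pmax(15, stats::rnorm(n, 25.51, 4.04))
  weight <- bmi * height^2
  nses <- stats::rnorm(n, -0.61, 1.08)
  income <- pmax(0, stats::rnorm(n, 1641.75, 517.12))
  education <- factor(sample(c("low", "middle", "high"), n, replace = TRUE,
                             prob = c(0.255, 0.408, 0.337)),
                      levels = c("low", "middle", "high"))
  occupation <- stats::rnorm(n, 43.88, 13.08)
  disease <- stats::rbinom(n, 1, 0.316)
  depression <- stats::rbinom(n, 1, 0.025)
  anxiety <- stats::rbinom(n, 1, 0.071)
  life_events <- stats::rnbinom(n, mu = 1.2, size = 3)
  long_term_difficulties <- stats::rnbinom(n, mu = 2.5, size = 2)
  neuro <- stats::rbinom(n, 1, 0.02)

  # -- raw diet/lifestyle ingredients --------------------------------------
  gam <- config$rge_gamma
  mix <- function(z) sqrt(1 - gam^2) * z + gam * prs
  log_kcal <- log(1.28) + 0.24 * mix(stats::rnorm(n))
  log_fat <- log(1.18) + 0.125 * mix(stats::rnorm(n))
  log_sugar <- log(1.06) + 0.45 * mix(stats::rnorm(n))
  quality <- sqrt(1 - gam^2) * stats::rnorm(n) - gam * prs

  pol <- llds_polarity()
  base_intake <- c(vegetables = 80, fruits = 70, whole_grains = 60,
                   legumes_nuts = 15, fish = 10, oils_soft_margarine = 10,
                   unsweetened_dairy = 100, coffee = 300, tea = 200,
                   red_processed_meat = 50, butter_hard_margarine = 5,
                   sugar_sweetened_beverages = 50)
  groups <- sapply(names(pol), function(gname) {
    exp(log(base_intake[[gname]]) +
          0.6 * (sqrt(0.95) * stats::rnorm(n) +
                   sqrt(0.05) * pol[[gname]] * quality))
  })
  groups <- as.data.frame(groups)

  bmr <- schofield_bmr(age, as.character(sex), weight, height)
  energy <- exp(log_kcal) * bmr
  fat_pct <- pmin(95, 30 * exp(log_fat))
  sugar_pct <- pmin(60, 10 * exp(log_sugar))

  mvpa_min <- ifelse(stats::runif(n) < 0.05, 0,
                     exp(stats::rnorm(n, log(190), 1.05)))
  sleep_hours <- 7.32 + 0.28 * (sex == "female") - 0.008 * (age - 42.1) +
    stats::rnorm(n, 0, 0.80)
  alcohol_g <- ifelse(stats::runif(n) < 0.157, 0,
                      exp(stats::rnorm(n, 1.87, 1.3)))
  smoke_draw <- sample(c("never", "past", "current"), n, replace = TRUE,
                       prob = c(0.491, 0.316, 0.193))
  current_smoker <- smoke_draw == "current"
  smoked_ge_1yr <- smoke_draw != "never"

  # -- derived variables via the derivation module -------------------------
  reliable <- energy_reliability(energy, bmr)
  kcal <- fat <- sugar <- rep(NA_real_, n)
  ex <- excess_ratios(energy[reliable], bmr[reliable],
                      fat_pct[reliable], sugar_pct[reliable])
  kcal[reliable] <- ex$kcal
  fat[reliable] <- ex$fat
  sugar[reliable] <- ex$sugar

  lv <- llds(groups[reliable, , drop = FALSE])
  llds_v <- llds_i_v <- rep(NA_real_, n)
  llds_v[reliable] <- lv$llds
  llds_i_v[reliable] <- lv$llds_i

  tert <- function(x) {
    out <- factor(rep(NA_character_, n), levels = c("Q1", "Q2", "Q3"))
    out[reliable] <- tertile_groups(x[reliable])
    out
  }
  kcal_tertile <- tert(kcal)
  fat_tertile <- tert(fat)
  llds_i_tertile <- tert(llds_i_v)
  sugar_group <- factor(rep(NA_character_, n), levels = c("Q1", "Q2"))
  sugar_group[reliable] <- binary_sugar(sugar[reliable])

  mvpaq <- mvpa_quintile(mvpa_min)
  sleep <- sleep_class(sleep_hours, age, as.character(sex))
  alcohol_cl <- alcohol_class(alcohol_g)
  smoking <- smoking_class(current_smoker, smoked_ge_1yr)

  # -- outcome -------------------------------------------------------------
  ind <- function(x) ifelse(is.na(x), 0, as.numeric(x))
  term_column <- function(term) {
    if (startsWith(term, "prs_x_"))
      return(prs * term_column(sub("^prs_x_", "", term)))
    switch(term,
      prs = prs, age = age, sex_female = as.numeric(sex == "female"),
      bmi = bmi, neighborhood_ses = nses, income = income,
      edu_middle = as.numeric(education == "middle"),
      edu_high = as.numeric(education == "high"),
      occupation = occupation, disease = disease,
      life_events = life_events,
      long_term_difficulties = long_term_difficulties,
      depression = depression, anxiety = anxiety,
      llds_i_q2 = ind(llds_i_tertile == "Q2"),
      llds_i_q3 = ind(llds_i_tertile == "Q3"),
      kcal_q2 = ind(kcal_tertile == "Q2"),
      kcal_q3 = ind(kcal_tertile == "Q3"),
      fat_q2 = ind(fat_tertile == "Q2"),
      fat_q3 = ind(fat_tertile == "Q3"),
      sugar_q2 = ind(sugar_group == "Q2"),
      sleep_short = as.numeric(sleep == "short"),
      sleep_long = as.numeric(sleep == "long"),
      smoking_current = as.numeric(smoking == "current"),
      smoking_past = as.numeric(smoking == "past"),
      alcohol_occasional = as.numeric(alcohol_cl == "occasional"),
      alcohol_light = as.numeric(alcohol_cl == "light"),
      alcohol_moderate = as.numeric(alcohol_cl == "moderate"),
      alcohol_heavy = as.numeric(alcohol_cl == "heavy"),
      mvpaq = as.numeric(mvpaq),
      stop("configuration error: unknown outcome term '", term, "'")
    )
  }

  coefs <- config$outcome_coefficients
  lp <- rep(0, n)
  for (term in names(coefs)) lp <- lp + coefs[[term]] * term_column(term)
  lp <- lp - mean(lp)

  rsd <- config$residual_sd
  if (is.null(rsd)) {
    v <- stats::var(lp)
    if (v >= 0.99)
      stop("outcome_coefficients imply a systematic variance >= 0.99; ",
           "supply residual_sd explicitly")
    rsd <- sqrt(1 - v)
  }
  y <- lp + stats::rnorm(n, 0, rsd)

  # -- back-filled NEO facet sums consistent with the outcome --------------
  ys <- as.numeric(scale(y))
  fac_r <- c(impulsivity_facet = 0.81, excitement_seeking = 0.37,
             deliberateness = 0.82, self_discipline = 0.68)
  oriented <- sapply(names(fac_r), function(f) {
    24 + 5 * (fac_r[[f]] * ys + sqrt(1 - fac_r[[f]]^2) * stats::rnorm(n))
  })
  facets <- data.frame(
    impulsivity_facet = .clamp_facet(oriented[, "impulsivity_facet"]),
    excitement_seeking = .clamp_facet(oriented[, "excitement_seeking"]),
    deliberateness = .clamp_facet(48 - oriented[, "deliberateness"]),
    self_discipline = .clamp_facet(48 - oriented[, "self_discipline"])
  )

  cohort <- data.frame(
    sample_id = genotypes$samples$sample_id,
    age = age, sex = sex, height = height, weight = weight, bmi = bmi,
    neighborhood_ses = nses, income = income, education = education,
    occupation = occupation, disease = disease, depression = depression,
    anxiety = anxiety, life_events = life_events,
    long_term_difficulties = long_term_difficulties,
    neurological_disorder = neuro,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, groups)
  cohort$energy_kcal <- energy
  cohort$fat_pct <- fat_pct
  cohort$sugar_pct <- sugar_pct
  cohort$mvpa_min <- mvpa_min
  cohort$sleep_hours <- sleep_hours
  cohort$alcohol_g <- alcohol_g
  cohort$current_smoker <- current_smoker
  cohort$smoked_ge_1yr <- smoked_ge_1yr
  cohort$chip <- genotypes$samples$chip
  cohort$pc1 <- genotypes$samples$pc1
  cohort$pc2 <- genotypes$samples$pc2
  cohort$pc3 <- genotypes$samples$pc3
  cohort$pc4 <- genotypes$samples$pc4
  cohort <- cbind(cohort, facets)
  cohort$bmr <- bmr
  cohort$energy_reliable <- reliable
  cohort$kcal <- kcal
  cohort$fat <- fat
  cohort$sugar <- sugar
  cohort$llds <- llds_v
  cohort$llds_i <- llds_i_v
  cohort$kcal_tertile <- kcal_tertile
  cohort$fat_tertile <- fat_tertile
  cohort$llds_i_tertile <- llds_i_tertile
  cohort$sugar_group <- sugar_group
  cohort$mvpaq <- mvpaq
  cohort$sleep_class <- sleep
  cohort$alcohol_class <- alcohol_cl
  cohort$smoking <- smoking
  cohort$prs <- prs
  cohort$impulsivity <- y

  truth <- list(coefficients = coefs, residual_sd = rsd,
                systematic_variance = stats::var(lp),
                rge_gamma = gam, seed = config$seed,
                n_samples = n, beta_true = tr)

  structure(list(genotypes = genotypes, summary_stats = summary_stats,
                 cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' Simulate a full synthetic cohort in one call
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_summary_stats()] and [simulate_cohort_table()].
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` object.
#' @export
simulate_cohort <- function(config) {
  gt <- simulate_genotypes(config)
  ss <- simulate_summary_stats(gt, config)
  simulate_cohort_table(gt, ss, config)
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits the genotype dosages (TSV or VCF 4.2 with a DS field), the
#' summary-statistics TSV, the cohort CSV, the generating truth as YAML, and
#' a manifest listing files, seed and md5 checksums.
#'
#' @param sc A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @param format `"tsv"` (dosage matrix + variant/sample sidecars) or
#'   `"vcf"`.
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(sc, dir, format = c("tsv", "vcf")) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  files <- character(0)
  if (format == "tsv") {
    write_genotypes_tsv(sc$genotypes, file.path(dir, "dosages.tsv"),
                        file.path(dir, "variants.tsv"),
                        file.path(dir, "samples.tsv"))
    files <- c(files, "dosages.tsv", "variants.tsv", "samples.tsv")
  } else {
    write_vcf(sc$genotypes, file.path(dir, "genotypes.vcf"))
    write_samples_tsv(sc$genotypes, file.path(dir, "samples.tsv"))
    files <- c(files, "genotypes.vcf", "samples.tsv")
  }
  write_summary_stats(sc$summary_stats, file.path(dir, "summary_stats.tsv"))
  write_cohort(sc$cohort, file.path(dir, "cohort.csv"))
  tr <- sc$truth
  tr$coefficients <- as.list(tr$coefficients)
  tr$beta_true <- NULL
  yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  files <- c(files, "summary_stats.tsv", "cohort.csv", "truth.yaml")

  manifest <- list(
    seed = sc$truth$seed,
    n_samples = sc$truth$n_samples,
    n_variants = nrow(sc$genotypes$variants),
    format = format,
    files = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$files) <- files
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
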