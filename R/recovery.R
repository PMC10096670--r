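# Parameter-recovery simulation drivers: repeatedly generate cohorts under a
# named generating-coefficient block and refit the corresponding model.

.analysis_subset <- function(cohort) {
  cohort[cohort$energy_reliable & cohort$neurological_disorder == 0 &
           !is.na(cohort$impulsivity) & !is.na(cohort$llds_i), ,
         drop = FALSE]
}

#' Coefficient-recovery simulation study
#'
#' Generates `n_reps` independent cohorts under the generating coefficients
#' of `block` (see [generating_coefficients()]), applies the standard sample
#' exclusions, fits the step-1 basic model (no moderator) or the step-2
#' model for `moderator`, and returns the estimate of `term` from each
#' replicate. Replicate seeds are derived from `seed` so the study is
#' reproducible end to end.
#'
#' @param block Generating-coefficient block name.
#' @param term Fitted-model term to extract (e.g. `"prs"` or
#'   `"prs:kcal_tertileQ3"`).
#' @param moderator `NULL` for the basic model, else a
#'   [step2_moderators()] key.
#' @param n_reps Number of replicates.
#' @param n_samples Cohort size per replicate.
#' @param seed Root seed.
#' @param n_variants,n_blocks Genotype panel size (the score enters the
#'   outcome as a standardized variable, so a modest panel suffices).
#' @param prs_coefficient Optional override of the generating `prs`
#'   coefficient.
#' @return Numeric vector of per-replicate estimates.
#' @export
replicate_recovery <- function(block, term, moderator = NULL, n_reps = 50,
                               n_samples = 33047, seed = 1,
                               n_variants = 120, n_blocks = 12,
                               prs_coefficient = NULL) {
  coefs <- generating_coefficients(block)
  if (!is.null(prs_coefficient)) coefs[["prs"]] <- prs_coefficient
  vapply(seq_len(n_reps), function(i) {
    cfg <- simulation_config(n_samples = n_samples, n_variants = n_variants,
                             n_blocks = n_blocks,
                             outcome_coefficients = coefs,
                             seed = derive_seed(seed, 1000 + i))
    sc <- simulate_cohort(cfg)
    d <- .analysis_subset(sc$cohort)
    fit <- if (is.null(moderator)) fit_linear(d) else fit_step2(d, moderator)
    est <- fit$terms$B[fit$terms$term == term]
    if (length(est) != 1)
      stop("term '", term, "' not found in fitted model")
    est
  }, numeric(1))
}

#' Variance-explained recovery simulation study
#'
#' Generates cohorts in which the polygenic score accounts for a fixed
#' `share` of the outcome variance remaining after residualization on age,
#' sex and the genetic controls (see [prs_coef_for_share()]), runs
#' [two_step_r2()] on each, and returns the per-replicate adjusted R^2 in
#' percent.
#'
#' @param share Target residualized variance share (fraction).
#' @inheritParams replicate_recovery
#' @return Numeric vector of per-replicate variance-explained percentages.
#' @export
replicate_r2 <- function(share = 0.0039, n_reps = 50, n_samples = 33047,
                         seed = 1, n_variants = 120, n_blocks = 12) {
  coefs <- c(prs = prs_coef_for_share(share),
             age = -0.021, sex_female = 0.036)
  vapply(seq_len(n_reps), function(i) {
    cfg <- simulation_config(n_samples = n_samples, n_variants = n_variants,
                             n_blocks = n_blocks,
                             outcome_coefficients = coefs,
                             seed = derive_seed(seed, 2000 + i))
    sc <- simulate_cohort(cfg)
    two_step_r2(sc$cohort)$variance_explained_pct
  }, numeric(1))
}
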