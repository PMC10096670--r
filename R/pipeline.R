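# End-to-end orchestration: simulate (optional) -> summary-statistic QC ->
# clumping -> multi-threshold scoring -> PRS-PCA -> derived variables ->
# exclusions -> model battery -> variance explained -> sensitivity -> rGE.

#' Run configuration
#'
#' Bundles the filter constants, threshold grid, model settings and
#' (optionally) a [simulation_config()]. Constants default to the analysis'
#' published values: MAF > 0.01, INFO > 0.8, clumping r^2 < 0.1 in a 250 kb
#' window, energy-reporting reliability bounds 0.79-2.49, WHO fat/sugar
#' maxima 30%/10%, Bonferroni level 0.0125.
#'
#' @param sim A [simulation_config()], or `NULL` to read inputs from
#'   `paths`.
#' @param paths Named list of input paths (`summary_stats`, `dosages`,
#'   `variants`, `samples`, `cohort`) when not simulating.
#' @param out_dir Output directory for artifacts (`NULL`: write nothing).
#' @param thresholds P-value threshold grid.
#' @param maf_min,info_min,r2_max,window_kb Filter constants.
#' @param alpha Significance level for flags.
#' @param seed Root seed (defaults to the simulation seed when simulating).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), paths = NULL,
                       out_dir = NULL,
                       thresholds = default_prs_thresholds(),
                       maf_min = 0.01, info_min = 0.8, r2_max = 0.1,
                       window_kb = 250, alpha = bonferroni_alpha(),
                       seed = if (!is.null(sim)) sim$seed else 1) {
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths must be supplied")
  structure(list(sim = sim, paths = paths, out_dir = out_dir,
                 thresholds = thresholds, maf_min = maf_min,
                 info_min = info_min, r2_max = r2_max,
                 window_kb = window_kb, alpha = alpha, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on simulated or loaded inputs: summary-statistic
#' quality control against the target panel, greedy LD clumping,
#' multi-threshold scoring, PRS-PCA aggregation, merging the aggregated
#' score into the cohort, sample exclusions (age >= 18, no neurological
#' disorder, reliable energy reporting, complete outcome and diet), the
#' step-1 basic model, the four step-2a diet and four step-2b lifestyle
#' interaction models, the two-step variance-explained procedure, the
#' SES-interaction sensitivity models for the diet moderators, and the
#' gene-environment correlation table. Record counts are tracked at every
#' exclusion so the run manifest reproduces a flowchart-style accounting.
#'
#' @param config A [run_config()].
#' @return A list with `manifest` (config echo, seed, stage record counts,
#'   file checksums), `prs` (`prs_score`), `data` (analysis cohort),
#'   `fits` (named `gxe_fit` list), `r2`, `sensitivity`, `rge`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$sim)) {
    gt <- simulate_genotypes(config$sim)
    ss <- simulate_summary_stats(gt, config$sim)
    sc <- simulate_cohort_table(gt, ss, config$sim)
    cohort <- sc$cohort
  } else {
    p <- config$paths
    gt <- read_genotypes_tsv(p$dosages, p$variants, p$samples)
    ss <- read_summary_stats(p$summary_stats)
    cohort <- read_cohort(p$cohort)
  }

  counts <- list(variants_in = nrow(ss), records_in = nrow(cohort))

  ss_qc <- qc_summary_stats(ss, maf_min = config$maf_min,
                            info_min = config$info_min, target = gt)
  counts$variants_post_qc <- nrow(ss_qc)
  ss_clumped <- ld_clump(ss_qc, gt, r2_max = config$r2_max,
                         window_kb = config$window_kb)
  counts$variants_post_clump <- nrow(ss_clumped)

  panel <- suppressWarnings(
    score_prs(gt, ss_clumped, thresholds = config$thresholds))
  prs <- prs_pca(panel)
  cohort$prs_pca <- prs$score[match(cohort$sample_id,
                                    gt$samples$sample_id)]

  # staged exclusions with flowchart-style accounting
  stage <- function(d, keep, label) {
    kept <- d[keep, , drop = FALSE]
    counts[[label]] <<- nrow(kept)
    kept
  }
  d <- cohort
  d <- stage(d, d$age >= 18, "after_age_18")
  d <- stage(d, d$neurological_disorder == 0, "after_neuro_exclusion")
  d <- stage(d, !is.na(d$impulsivity) & !is.na(d$llds_i),
             "after_complete_outcome_diet")
  d <- stage(d, d$energy_reliable, "analysis_sample")

  fits <- list(basic = fit_linear(d, alpha = config$alpha))
  for (m in c("llds_i", "kcal", "fat", "sugar"))
    fits[[paste0("step2a_", m)]] <- fit_step2(d, m, alpha = config$alpha)
  for (m in c("sleep", "smoking", "alcohol", "mvpa"))
    fits[[paste0("step2b_", m)]] <- fit_step2(d, m, alpha = config$alpha)

  r2 <- two_step_r2(d)
  sens <- lapply(stats::setNames(nm = c("llds_i", "kcal", "fat", "sugar")),
                 function(m) sensitivity_ses(d, m, alpha = config$alpha))
  rge <- rge_correlations(d$prs,
                          d[, c("llds_i", "kcal", "fat", "sugar",
                                "sleep_hours", "mvpa_min", "alcohol_g",
                                "current_smoker")])

  manifest <- list(seed = config$seed, counts = counts,
                   thresholds = config$thresholds,
                   filters = list(maf_min = config$maf_min,
                                  info_min = config$info_min,
                                  r2_max = config$r2_max,
                                  window_kb = config$window_kb,
                                  alpha = config$alpha),
                   n_model_tables = length(fits),
                   r_version = as.character(getRversion()))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- report_tables(fits, config$out_dir)
    utils::write.csv(rge, file.path(config$out_dir, "rge_correlations.csv"),
                     row.names = FALSE)
    cfg <- config
    if (!is.null(cfg$sim)) {
      cfg$sim <- unclass(cfg$sim)
      cfg$sim$outcome_coefficients <- as.list(cfg$sim$outcome_coefficients)
    }
    write_yaml_config(unclass(cfg)[setdiff(names(cfg), "paths")],
                      file.path(config$out_dir, "run_config.yaml"))
    manifest$config_md5 <- unname(
      tools::md5sum(file.path(config$out_dir, "run_config.yaml")))
    manifest$files <- as.list(tools::md5sum(
      c(paths, file.path(config$out_dir, "rge_correlations.csv"))))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }

  list(manifest = manifest, prs = prs, data = d, fits = fits, r2 = r2,
       sensitivity = sens, rge = rge)
}
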