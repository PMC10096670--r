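# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A mid-sized cohort under the basic generating model, reused across files.
shared_cohort <- function() {
  if (is.null(.fixture_env$sc)) {
    cfg <- simulation_config(n_samples = 3000, n_variants = 60,
                             n_blocks = 10, seed = 101)
    .fixture_env$sc <- simulate_cohort(cfg)
  }
  .fixture_env$sc
}

# Minimal clean summary-stats table for QC/scoring unit tests.
toy_summary_stats <- function(n = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    chr = "1", pos = seq_len(n) * 1000L,
    a1 = rep("A", n), a2 = rep("C", n),
    beta = round(stats::rnorm(n, 0, 0.05), 4),
    p = round(stats::runif(n), 4),
    freq = round(stats::runif(n, 0.05, 0.5), 3),
    info = 1.0, stringsAsFactors = FALSE
  )
}

# Genotype panel built directly from a dosage matrix (columns = variants).
toy_genotypes <- function(D, chrom = "1", pos = NULL,
                          effect = "A", other = "C") {
  m <- ncol(D)
  n <- nrow(D)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  ids <- colnames(D)
  if (is.null(ids)) {
    ids <- sprintf("rs%03d", seq_len(m))
    colnames(D) <- ids
  }
  rownames(D) <- sprintf("S%04d", seq_len(n))
  structure(list(
    dosages = D,
    variants = data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                          effect_allele = rep_len(effect, m),
                          other_allele = rep_len(other, m),
                          maf = colMeans(D) / 2, info = 1.0,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(D),
                         chip = rep("chipA", n),
                         pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0,
                         stringsAsFactors = FALSE)
  ), class = "genotype_data")
}

# Independent brute-force clumping oracle: full pairwise r^2 matrix, then
# straightforward greedy selection. Kept deliberately separate from the
# package implementation.
brute_force_clump <- function(ss, ref, r2_max = 0.1, window_kb = 250) {
  m <- nrow(ss)
  col_of <- match(ss$snp, colnames(ref$dosages))
  R2 <- suppressWarnings(
    stats::cor(ref$dosages[, col_of, drop = FALSE],
               use = "pairwise.complete.obs"))^2
  R2[is.na(R2)] <- 0
  removed <- rep(FALSE, m)
  selected <- rep(FALSE, m)
  repeat {
    cand <- which(!removed & !selected)
    if (length(cand) == 0) break
    best <- cand[order(ss$p[cand], ss$pos[cand])][1]
    selected[best] <- TRUE
    for (j in which(!removed & !selected)) {
      if (ss$chr[j] == ss$chr[best] &&
          abs(ss$pos[j] - ss$pos[best]) <= window_kb * 1000 &&
          R2[best, j] >= r2_max) {
        removed[j] <- TRUE
      }
    }
  }
  ss$snp[selected]
}
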