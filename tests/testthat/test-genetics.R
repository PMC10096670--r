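test_that("summary-statistic QC removes exactly the offending variants", {
  # 6 distinct variants over 7 rows: one id duplicated (multiallelic
  # stand-in), one C/G ambiguous, one rare, one poorly imputed, two clean
  ss <- data.frame(
    snp = c("rs1", "rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    chr = "1", pos = c(1, 1, 2, 3, 4, 5, 6) * 1000L,
    a1 = c("A", "A", "C", "A", "A", "A", "T"),
    a2 = c("C", "G", "G", "C", "C", "C", "C"),
    beta = 0.1, p = 0.5,
    freq = c(0.3, 0.3, 0.3, 0.005, 0.3, 0.3, 0.3),
    info = c(1, 1, 1, 1, 0.5, 1, 1),
    stringsAsFactors = FALSE
  )
  out <- qc_summary_stats(ss)
  expect_setequal(out$snp, c("rs5", "rs6"))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$step == "multiallelic (duplicated id)"], 2)
  expect_equal(rep$removed[rep$step == "ambiguous strand (A/T, C/G)"], 1)
})

test_that("A/T variants are strand-ambiguous and removed", {
  ss <- toy_summary_stats(3)
  ss$a1[2] <- "A"; ss$a2[2] <- "T"
  out <- qc_summary_stats(ss)
  expect_false("rs002" %in% out$snp)
  expect_setequal(out$snp, c("rs001", "rs003"))
})

test_that("QC handles empty input and reports missing columns", {
  ss <- toy_summary_stats(3)[0, ]
  out <- qc_summary_stats(ss)
  expect_equal(nrow(out), 0)
  expect_equal(sum(attr(out, "qc_report")$removed), 0)
  expect_error(qc_summary_stats(ss[, -6]), "format error")
})

test_that("QC against a target panel drops absent variants", {
  ss <- toy_summary_stats(4)
  D <- matrix(rbinom(20 * 2, 2, 0.3), 20, 2,
              dimnames = list(NULL, c("rs001", "rs003")))
  gt <- toy_genotypes(D)
  out <- qc_summary_stats(ss, target = gt)
  expect_setequal(out$snp, c("rs001", "rs003"))
})

test_that("clumping keeps the most significant of two correlated variants", {
  set.seed(20)
  x <- rbinom(500, 2, 0.3)
  D <- cbind(rs001 = x, rs002 = x)  # perfectly correlated, 1 kb apart
  gt <- toy_genotypes(D, pos = c(10000L, 11000L))
  ss <- toy_summary_stats(2)
  ss$pos <- c(10000L, 11000L)
  ss$p <- c(1e-4, 1e-8)
  out <- ld_clump(ss, gt)
  expect_equal(out$snp, "rs002")
})

test_that("perfect LD outside the window leaves both variants", {
  set.seed(21)
  x <- rbinom(500, 2, 0.3)
  gt <- toy_genotypes(cbind(rs001 = x, rs002 = x),
                      pos = c(1L, 600000L))
  ss <- toy_summary_stats(2)
  ss$pos <- c(1L, 600000L)
  out <- ld_clump(ss, gt)
  expect_setequal(out$snp, c("rs001", "rs002"))
})

test_that("clumping errors on variants missing from the reference", {
  gt <- toy_genotypes(matrix(rbinom(40, 2, 0.3), 20, 2,
                             dimnames = list(NULL, c("rs001", "rs002"))))
  ss <- toy_summary_stats(3)
  expect_error(ld_clump(ss, gt), "rs003")
})

test_that("greedy clumping matches the brute-force oracle on random fixtures", {
  for (rep_i in 1:12) {
    cfg <- simulation_config(n_samples = 300,
                             n_variants = sample(10:50, 1),
                             n_blocks = sample(2:5, 1),
                             block_r = runif(1, 0, 0.7),
                             ambiguous_fraction = 0, duplicate_n = 0,
                             seed = 300 + rep_i)
    gt <- simulate_genotypes(cfg)
    ss <- simulate_summary_stats(gt, cfg)
    r2_max <- sample(c(0.05, 0.1, 0.3), 1)
    got <- ld_clump(ss, gt, r2_max = r2_max)$snp
    want <- brute_force_clump(ss, gt, r2_max = r2_max)
    expect_setequal(got, want)
  }
})

test_that("single-variant scoring arithmetic is exact", {
  gt <- toy_genotypes(cbind(rs001 = c(0, 1, 2)))
  ss <- toy_summary_stats(1)
  ss$beta <- log(1.2)
  ss$p <- 0.5
  panel <- suppressWarnings(score_prs(gt, ss, thresholds = c(0.01, 1)))
  expect_equal(unname(panel$raw_scores[, 2]),
               c(0, 0.1823, 0.3646), tolerance = 1e-3)
  expect_equal(panel$snp_counts, c(0L, 1L))
  expect_true(panel$degenerate[1])  # empty threshold flagged
})

test_that("multi-variant scores match a hand-computed matrix", {
  D <- rbind(c(0, 1, 2, 0, 1),
             c(2, 2, 0, 1, 0),
             c(1, 0, 1, 2, 2),
             c(0, 0, 0, 0, 0))
  colnames(D) <- sprintf("rs%03d", 1:5)
  gt <- toy_genotypes(D)
  ss <- toy_summary_stats(5)
  ss$beta <- c(0.1, -0.2, 0.05, 0.3, -0.15)
  ss$p <- c(1e-9, 1e-6, 1e-3, 0.04, 0.9)
  panel <- score_prs(gt, ss, thresholds = c(5e-8, 1e-5, 0.05, 1))
  # p <= 5e-8: variant 1 only; p <= 1e-5: 1,2; p <= 0.05: 1..4; all: 1..5
  expect_equal(unname(panel$raw_scores[, 1]), c(0, 0.2, 0.1, 0))
  expect_equal(unname(panel$raw_scores[, 2]),
               c(0 - 0.2, 0.2 - 0.4, 0.1 - 0, 0))
  expect_equal(unname(panel$raw_scores[, 3]),
               c(0.1 * 0 - 0.2 * 1 + 0.05 * 2 + 0.3 * 0,
                 0.1 * 2 - 0.2 * 2 + 0.05 * 0 + 0.3 * 1,
                 0.1 * 1 - 0.2 * 0 + 0.05 * 1 + 0.3 * 2,
                 0))
  expect_equal(panel$snp_counts, c(1L, 2L, 4L, 5L))
  expect_true(all(diff(panel$snp_counts) >= 0))
  # standardized columns have mean 0, sd 1
  ok <- !panel$degenerate
  expect_equal(unname(colMeans(panel$scores[, ok])), rep(0, sum(ok)),
               tolerance = 1e-8)
  expect_equal(unname(apply(panel$scores[, ok], 2, sd)), rep(1, sum(ok)),
               tolerance = 1e-8)
})

test_that("zero weights give a degenerate flagged panel", {
  gt <- toy_genotypes(cbind(rs001 = c(0, 1, 2), rs002 = c(2, 1, 0)))
  ss <- toy_summary_stats(2)
  ss$beta <- 0
  expect_warning(panel <- score_prs(gt, ss, thresholds = c(0.5, 1)),
                 "degenerate")
  expect_true(all(panel$degenerate))
  expect_true(all(panel$raw_scores == 0))
})

test_that("allele harmonization flips swapped alleles and rejects mismatches", {
  D <- cbind(rs001 = c(0, 1, 2))
  gt <- toy_genotypes(D, effect = "A", other = "C")
  ss <- toy_summary_stats(1)
  ss$beta <- 0.5
  ss$a1 <- "C"; ss$a2 <- "A"  # effect allele is the panel's other allele
  panel <- score_prs(gt, ss, thresholds = c(1))
  expect_equal(unname(panel$raw_scores[, 1]), 0.5 * (2 - c(0, 1, 2)))
  ss$a1 <- "G"; ss$a2 <- "T"
  expect_error(score_prs(gt, ss, thresholds = c(1)), "rs001")
})

test_that("scoring is linear over sample concatenation", {
  cfg <- simulation_config(n_samples = 80, n_variants = 20, n_blocks = 4,
                           ambiguous_fraction = 0, duplicate_n = 0,
                           seed = 23)
  gt <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(gt, cfg)
  top <- function(g, rows) {
    g$dosages <- g$dosages[rows, , drop = FALSE]
    g$samples <- g$samples[rows, , drop = FALSE]
    g
  }
  th <- c(0.05, 0.5, 1)
  whole <- suppressWarnings(score_prs(gt, ss, thresholds = th))$raw_scores
  a <- suppressWarnings(score_prs(top(gt, 1:30), ss, thresholds = th))$raw_scores
  b <- suppressWarnings(score_prs(top(gt, 31:80), ss, thresholds = th))$raw_scores
  expect_equal(unname(whole), unname(rbind(a, b)))
})

test_that("PRS-PCA handles the rank-1 case and reports full variance", {
  set.seed(24)
  x <- rnorm(100)
  panel <- structure(list(scores = cbind(a = scale(x)[, 1],
                                         b = scale(x)[, 1]),
                          raw_scores = cbind(x, x),
                          thresholds = c(0.5, 1), snp_counts = c(1L, 1L),
                          degenerate = c(FALSE, FALSE)),
                     class = "prs_panel")
  out <- prs_pca(panel)
  expect_equal(out$loadings[[1]], out$loadings[[2]], tolerance = 1e-12)
  expect_equal(out$variance_explained, 1)
  expect_equal(mean(out$score), 0, tolerance = 1e-12)
  expect_equal(sd(out$score), 1, tolerance = 1e-12)
})

test_that("PRS-PCA is invariant to column sign flips and column order", {
  cfg <- simulation_config(n_samples = 400, n_variants = 60, n_blocks = 10,
                           seed = 25)
  gt <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(gt, cfg)
  ssq <- qc_summary_stats(ss, target = gt)
  panel <- suppressWarnings(score_prs(gt, ld_clump(ssq, gt)))
  base <- prs_pca(panel)

  # flipping the orientation of a few columns leaves the score unchanged;
  # reversing the whole panel mirrors it (the mean-loading convention then
  # re-orients), so the score agrees up to sign
  flipped <- panel
  flip_cols <- c(1, 4, 7)
  flipped$scores[, flip_cols] <- -panel$scores[, flip_cols]
  expect_equal(prs_pca(flipped)$score, base$score, tolerance = 1e-10)
  reversed <- panel
  reversed$scores <- -panel$scores
  expect_equal(abs(prs_pca(reversed)$score), abs(base$score),
               tolerance = 1e-10)

  perm <- sample(ncol(panel$scores))
  shuffled <- panel
  shuffled$scores <- panel$scores[, perm]
  shuffled$thresholds <- panel$thresholds[perm]
  shuffled$degenerate <- panel$degenerate[perm]
  expect_equal(prs_pca(shuffled)$score, base$score, tolerance = 1e-10)
})

test_that("PRS-PCA matches an independent eigen-decomposition", {
  cfg <- simulation_config(n_samples = 500, n_variants = 80, n_blocks = 10,
                           seed = 26)
  gt <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(gt, cfg)
  panel <- suppressWarnings(
    score_prs(gt, ld_clump(qc_summary_stats(ss, target = gt), gt)))
  out <- prs_pca(panel)

  X <- panel$scores[, !panel$degenerate, drop = FALSE]
  e <- eigen(cor(X), symmetric = TRUE)
  proj <- scale(X) %*% e$vectors[, 1]
  oracle <- as.numeric(scale(proj))
  expect_lt(min(sum(abs(out$score - oracle)),
                sum(abs(out$score + oracle))) / length(oracle), 1e-10)
})

test_that("PRS-PCA refuses fewer than two usable columns", {
  panel <- structure(list(scores = cbind(a = rnorm(10), b = 0),
                          thresholds = c(0.5, 1), snp_counts = c(1L, 0L),
                          degenerate = c(FALSE, TRUE)),
                     class = "prs_panel")
  expect_error(prs_pca(panel), "single-threshold")
})

test_that("rGE correlations recover self, null and constant cases", {
  set.seed(27)
  prs <- rnorm(10000)
  tab <- rge_correlations(prs, data.frame(self = prs,
                                          indep = rnorm(10000),
                                          fixed = rep(1, 10000)))
  expect_equal(tab$r[tab$exposure == "self"], 1, tolerance = 1e-12)
  expect_lt(abs(tab$r[tab$exposure == "indep"]), 0.03)
  expect_true(is.na(tab$r[tab$exposure == "fixed"]))
  expect_match(tab$note[tab$exposure == "fixed"], "constant")
})

test_that("the aggregated score tracks the true polygenic score end to end", {
  cfg <- simulation_config(n_samples = 5000, n_variants = 100,
                           n_blocks = 20, causal_fraction = 0.5,
                           effect_sd = 0.08, seed = 28)
  gt <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(gt, cfg)
  sc <- simulate_cohort_table(gt, ss, cfg)
  panel <- suppressWarnings(
    score_prs(gt, ld_clump(qc_summary_stats(ss, target = gt), gt)))
  agg <- prs_pca(panel)
  ct <- cor.test(agg$score, sc$cohort$prs)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
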