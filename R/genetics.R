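# Summary-statistic QC, greedy LD clumping, multi-threshold polygenic
# scoring and PRS-PCA aggregation.

.ss_required_cols <- c("snp", "chr", "pos", "a1", "a2", "beta", "p",
                       "freq", "info")

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality control of GWAS summary statistics
#'
#' Removes, in order: all copies of duplicated variant ids (multiallelic
#' stand-ins), strand-ambiguous variants (A/T or C/G allele pairs), variants
#' with minor allele frequency at or below `maf_min` or imputation INFO at
#' or below `info_min`, and - when a target genotype panel is supplied -
#' variants absent from that panel. A per-step filter-count report is
#' attached as attribute `"qc_report"`.
#'
#' @param ss Summary statistics data frame (columns `snp`, `chr`, `pos`,
#'   `a1`, `a2`, `beta`, `p`, `freq`, `info`).
#' @param maf_min Minimum minor allele frequency (exclusive bound; the kept
#'   set satisfies MAF > `maf_min`).
#' @param info_min Minimum INFO (exclusive bound).
#' @param target Optional `genotype_data`; variants not present in it are
#'   dropped.
#' @return Filtered summary statistics with a `qc_report` attribute.
#' @export
qc_summary_stats <- function(ss, maf_min = 0.01, info_min = 0.8,
                             target = NULL) {
  miss <- setdiff(.ss_required_cols, names(ss))
  if (length(miss) > 0)
    stop("format error: required column(s) missing: ",
         paste(miss, collapse = ", "))
  truth <- attr(ss, "truth")
  n0 <- nrow(ss)
  report <- data.frame(step = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(step, before, after) {
    rbind(report, data.frame(step = step, removed = before - after,
                             remaining = after))
  }
  if (n0 == 0) {
    out <- ss
    attr(out, "qc_report") <- note("input", 0L, 0L)
    return(out)
  }

  dup_ids <- unique(ss$snp[duplicated(ss$snp)])
  keep <- !(ss$snp %in% dup_ids)
  out <- ss[keep, , drop = FALSE]
  report <- note("multiallelic (duplicated id)", n0, nrow(out))

  k <- !.is_ambiguous(out$a1, out$a2)
  n_prev <- nrow(out); out <- out[k, , drop = FALSE]
  report <- note("ambiguous strand (A/T, C/G)", n_prev, nrow(out))

  k <- pmin(out$freq, 1 - out$freq) > maf_min
  n_prev <- nrow(out); out <- out[k, , drop = FALSE]
  report <- note(sprintf("MAF <= %g", maf_min), n_prev, nrow(out))

  k <- out$info > info_min
  n_prev <- nrow(out); out <- out[k, , drop = FALSE]
  report <- note(sprintf("INFO <= %g", info_min), n_prev, nrow(out))

  if (!is.null(target)) {
    stopifnot(inherits(target, "genotype_data"))
    k <- out$snp %in% target$variants$id
    n_prev <- nrow(out); out <- out[k, , drop = FALSE]
    report <- note("absent from target panel", n_prev, nrow(out))
  }

  if (nrow(out) == 0)
    stop("no variants survive quality control")
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "qc_report") <- report
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Greedy LD clumping
#'
#' Repeatedly selects the unremoved variant with the smallest p-value as an
#' index (ties broken by smaller genomic position) and removes all
#' unselected variants on the same chromosome within +/- `window_kb` whose
#' squared dosage correlation with the index is at or above `r2_max`. The
#' survivors form an independent set: every pair within a window has
#' r^2 < `r2_max`. Correlations are computed on reference-panel dosages with
#' pairwise-complete observations.
#'
#' @param ss Summary statistics (post-QC).
#' @param ref `genotype_data` LD reference; every variant in `ss` must be
#'   present.
#' @param r2_max Squared-correlation removal threshold (removal uses >=).
#' @param window_kb Window half-width in kb, inclusive.
#' @return The index variants as a `summary_stats` data frame.
#' @export
ld_clump <- function(ss, ref, r2_max = 0.1, window_kb = 250) {
  stopifnot(inherits(ref, "genotype_data"))
  truth <- attr(ss, "truth")
  missing_ids <- setdiff(ss$snp, ref$variants$id)
  if (length(missing_ids) > 0)
    stop("variant(s) missing from reference panel: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) ", ...")
  m <- nrow(ss)
  if (m == 0) return(ss)

  ord <- order(ss$p, ss$chr, ss$pos)
  col_of <- match(ss$snp, colnames(ref$dosages))
  window <- window_kb * 1000
  state <- rep("free", m)  # free | index | removed

  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    near <- which(state == "free" & ss$chr == ss$chr[i] &
                    abs(ss$pos - ss$pos[i]) <= window)
    if (length(near) == 0) next
    r <- suppressWarnings(
      stats::cor(ref$dosages[, col_of[i]],
                 ref$dosages[, col_of[near], drop = FALSE],
                 use = "pairwise.complete.obs"))
    r2 <- as.numeric(r)^2
    r2[is.na(r2)] <- 0
    state[near[r2 >= r2_max]] <- "removed"
  }

  out <- ss[state == "index", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Multi-threshold polygenic scoring
#'
#' For each p-value threshold t, computes per-sample raw scores
#' sum over variants with p <= t of beta * dosage, after harmonizing the
#' counted allele: if the summary-statistic effect allele equals the
#' genotype panel's other allele (and vice versa) the dosage is flipped to
#' 2 - d; any other allele combination is an error (strand flips cannot
#' occur because ambiguous variants are removed in QC). Missing dosages are
#' imputed to the variant's mean dosage. Columns are then z-standardized;
#' zero-variance columns (e.g. no qualifying variants) are flagged
#' degenerate and excluded from later PCA with a warning.
#'
#' @param genotypes Target `genotype_data`.
#' @param ss Clumped summary statistics.
#' @param thresholds Increasing p-value thresholds
#'   (default [default_prs_thresholds()]).
#' @return An object of class `prs_panel`: list with `scores` (standardized
#'   n x T matrix; degenerate columns all zero), `raw_scores`, `thresholds`,
#'   `snp_counts`, `degenerate` (logical per column).
#' @export
score_prs <- function(genotypes, ss, thresholds = default_prs_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_data"))
  thresholds <- sort(thresholds)
  missing_ids <- setdiff(ss$snp, genotypes$variants$id)
  if (length(missing_ids) > 0)
    stop("variant(s) missing from genotype panel: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))

  vi <- match(ss$snp, genotypes$variants$id)
  ga1 <- genotypes$variants$effect_allele[vi]
  ga2 <- genotypes$variants$other_allele[vi]
  same <- ss$a1 == ga1 & ss$a2 == ga2
  flipped <- ss$a1 == ga2 & ss$a2 == ga1
  bad <- !(same | flipped)
  if (any(bad))
    stop("allele mismatch unresolvable for variant(s): ",
         paste(utils::head(ss$snp[bad], 10), collapse = ", "))

  D <- genotypes$dosages[, vi, drop = FALSE]
  if (anyNA(D)) {
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
    }
  }
  if (any(flipped)) D[, flipped] <- 2 - D[, flipped]

  n <- nrow(D)
  raw <- matrix(0, n, length(thresholds),
                dimnames = list(rownames(D),
                                paste0("p_", format(thresholds))))
  snp_counts <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    sel <- ss$p <= thresholds[k]
    snp_counts[k] <- sum(sel)
    if (any(sel))
      raw[, k] <- D[, sel, drop = FALSE] %*% ss$beta[sel]
  }

  sds <- apply(raw, 2, stats::sd)
  degenerate <- sds == 0
  scores <- raw
  scores[, !degenerate] <- scale(raw[, !degenerate, drop = FALSE])
  scores[, degenerate] <- 0
  if (any(degenerate))
    warning("degenerate score column(s) at threshold(s) ",
            paste(format(thresholds[degenerate]), collapse = ", "),
            "; excluded from PCA")

  structure(list(scores = scores, raw_scores = raw, thresholds = thresholds,
                 snp_counts = snp_counts, degenerate = degenerate),
            class = "prs_panel")
}

#' PRS-PCA aggregation across thresholds
#'
#' Extracts the first principal component of the column-standardized
#' multi-threshold score matrix as the final polygenic score, avoiding the
#' choice of a single threshold. The component is sign-fixed so the mean
#' loading is positive (higher score = higher risk) and re-standardized to
#' mean 0, sd 1.
#'
#' @param panel A `prs_panel` from [score_prs()].
#' @return An object of class `prs_score`: list with `score` (numeric per
#'   sample), `loadings` (per threshold; `NA` for degenerate columns),
#'   `variance_explained` (fraction of panel variance on the component) and
#'   `thresholds`.
#' @export
prs_pca <- function(panel) {
  stopifnot(inherits(panel, "prs_panel"))
  usable <- !panel$degenerate
  if (sum(usable) < 2)
    stop("fewer than 2 usable score columns; fall back to a ",
         "single-threshold score instead of PRS-PCA")
  X <- panel$scores[, usable, drop = FALSE]
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  v <- pr$rotation[, 1]
  s <- pr$x[, 1]
  if (mean(v) < 0) { v <- -v; s <- -s }
  score <- as.numeric(scale(s))
  loadings <- rep(NA_real_, length(panel$thresholds))
  loadings[usable] <- v
  names(loadings) <- paste0("p_", format(panel$thresholds))
  structure(list(score = score, loadings = loadings,
                 variance_explained = pr$sdev[1]^2 / sum(pr$sdev^2),
                 thresholds = panel$thresholds),
            class = "prs_score")
}

#' Gene-environment correlations
#'
#' Pearson correlation (with two-sided test) between the polygenic score and
#' each exposure column, as a measure of gene-environment correlation (rGE).
#' Complete cases are used per pair; a constant exposure yields `NA` with a
#' note.
#'
#' @param prs Numeric score vector or a `prs_score`.
#' @param exposures Data frame of exposures (numeric columns; factors are
#'   converted to their integer codes).
#' @return Data frame with columns `exposure`, `n`, `r`, `p`, `note`.
#' @export
rge_correlations <- function(prs, exposures) {
  if (inherits(prs, "prs_score")) prs <- prs$score
  stopifnot(is.numeric(prs), nrow(exposures) == length(prs))
  rows <- lapply(names(exposures), function(nm) {
    x <- exposures[[nm]]
    if (is.factor(x)) x <- as.numeric(x)
    if (is.logical(x)) x <- as.numeric(x)
    ok <- stats::complete.cases(prs, x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(prs[ok]) == 0) {
      return(data.frame(exposure = nm, n = sum(ok), r = NA_real_,
                        p = NA_real_, note = "constant or too few values",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(prs[ok], x[ok])
    data.frame(exposure = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
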