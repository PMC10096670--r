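# Readers and writers for the plain-text interchange formats: summary-stats
# TSV, dosage TSV (with variant/sample sidecars), VCF 4.2 with a DS field,
# cohort CSV and YAML configuration.

#' Write GWAS summary statistics as TSV
#'
#' Tab-delimited with the canonical header
#' `snp chr pos a1 a2 beta p freq info`.
#'
#' @param ss Summary statistics data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  miss <- setdiff(.ss_required_cols, names(ss))
  if (length(miss) > 0)
    stop("format error: required column(s) missing: ",
         paste(miss, collapse = ", "))
  utils::write.table(ss[, .ss_required_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Schema-validated: all nine columns must be present, alleles must be
#' single bases in \{A, C, G, T\} (violations are reported with their line
#' number) and p-values must lie in (0, 1\].
#'
#' @param path Input path.
#' @return A `summary_stats` data frame.
#' @export
read_summary_stats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.ss_required_cols, names(ss))
  if (length(miss) > 0)
    stop("format error: required column(s) missing: ",
         paste(miss, collapse = ", "))
  ss$snp <- as.character(ss$snp)
  ss$a1 <- as.character(ss$a1)
  ss$a2 <- as.character(ss$a2)
  bad <- which(!(ss$a1 %in% c("A", "C", "G", "T")) |
                 !(ss$a2 %in% c("A", "C", "G", "T")))
  if (length(bad) > 0)
    stop("malformed allele column at line ", bad[1] + 1L,
         " of ", path, " (alleles must be A/C/G/T)")
  bad_p <- which(!(ss$p > 0 & ss$p <= 1))
  if (length(bad_p) > 0)
    stop("p-value outside (0, 1] at line ", bad_p[1] + 1L, " of ", path)
  ss$chr <- as.character(ss$chr)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

#' Write genotype dosages and sidecars as TSV
#'
#' The dosage matrix is written samples x variants with a `sample_id`
#' column and a header row of variant ids; variant metadata and sample
#' metadata (chip label, genetic principal components) go to sidecar TSVs.
#'
#' @param gt A `genotype_data`.
#' @param dosage_path,variants_path,samples_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_genotypes_tsv <- function(gt, dosage_path, variants_path,
                                samples_path) {
  stopifnot(inherits(gt, "genotype_data"))
  d <- data.frame(sample_id = rownames(gt$dosages), gt$dosages,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gt$variants, variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_samples_tsv(gt, samples_path)
  invisible(c(dosage_path, variants_path, samples_path))
}

#' @rdname write_genotypes_tsv
#' @export
write_samples_tsv <- function(gt, samples_path) {
  utils::write.table(gt$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(samples_path)
}

#' Read genotype dosages and sidecars from TSV
#'
#' @param dosage_path,variants_path,samples_path Paths written by
#'   [write_genotypes_tsv()].
#' @return A `genotype_data`.
#' @export
read_genotypes_tsv <- function(dosage_path, variants_path, samples_path) {
  d <- utils::read.delim(dosage_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d))
    stop("format error: dosage TSV lacks a sample_id column")
  ids <- d$sample_id
  D <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  rownames(D) <- ids
  if (any(D < 0 | D > 2, na.rm = TRUE))
    stop("format error: dosages outside [0, 2]")
  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character"))
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (nrow(variants) != ncol(D))
    stop("format error: variant metadata length (", nrow(variants),
         ") does not match dosage columns (", ncol(D), ")")
  structure(list(dosages = D, variants = variants, samples = samples),
            class = "genotype_data")
}

#' Write genotypes as VCF 4.2 with dosage (DS) field
#'
#' One record per variant with `REF` = other allele, `ALT` = effect
#' (counted) allele, `INFO` carrying the allele frequency and INFO score,
#' and a `DS` FORMAT field holding the counted-allele dosage.
#'
#' @param gt A `genotype_data`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_data"))
  v <- gt$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gt$dosages)), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS",
            sprintf("AF=%.6g;INFO=%.6g", v$maf[j], v$info[j]), "DS",
            sprintf("%.6g", gt$dosages[, j])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF with DS field
#'
#' Parses a VCF 4.2 written by [write_vcf()] (or any VCF carrying a DS
#' FORMAT field) via the vcfR package; the ALT allele is taken as the
#' counted (effect) allele. Chip labels and genetic principal components
#' come from the samples sidecar TSV.
#'
#' @param vcf_path VCF path.
#' @param samples_path Samples sidecar TSV path.
#' @return A `genotype_data`.
#' @export
read_genotypes_vcf <- function(vcf_path, samples_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  D <- t(ds)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info <- vcf@fix[, "INFO"]
  getnum <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([0-9eE.+-]+).*"), "\\1", info))
  }
  variants <- data.frame(
    id = fix$ID, chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF,
    maf = getnum("AF"), info = getnum("INFO"), stringsAsFactors = FALSE
  )
  colnames(D) <- variants$id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  D <- D[match(samples$sample_id, rownames(D)), , drop = FALSE]
  structure(list(dosages = D, variants = variants, samples = samples),
            class = "genotype_data")
}

.cohort_factor_levels <- list(
  sex = c("male", "female"),
  education = c("low", "middle", "high"),
  kcal_tertile = c("Q1", "Q2", "Q3"),
  fat_tertile = c("Q1", "Q2", "Q3"),
  llds_i_tertile = c("Q1", "Q2", "Q3"),
  sugar_group = c("Q1", "Q2"),
  sleep_class = c("normal", "short", "long"),
  alcohol_class = c("abstinent", "occasional", "light", "moderate", "heavy"),
  smoking = c("never", "past", "current")
)

#' Write / read the cohort table as CSV
#'
#' Factors are stored as their labels; the reader restores the documented
#' level order (reference level first) for every categorical analysis
#' column it finds.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `path` (writer) or the cohort data frame (reader).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in names(.cohort_factor_levels)) {
    if (cn %in% names(d))
      d[[cn]] <- factor(d[[cn]], levels = .cohort_factor_levels[[cn]])
  }
  d
}

#' Read / write a YAML run configuration
#'
#' @param path YAML path.
#' @param config List to write.
#' @return The configuration list (reader) or `path` (writer).
#' @export
read_yaml_config <- function(path) yaml::read_yaml(path)

#' @rdname read_yaml_config
#' @export
write_yaml_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
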