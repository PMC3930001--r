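#' Minor allele frequency of one SNP
#'
#' Frequency of the rarer allele among non-missing genotypes.
#'
#' @param gm a [genotype_matrix()].
#' @param snp a SNP id (or column index).
#' @return A value in \[0, 0.5\].
#' @export
compute_maf <- function(gm, snp) {
  j <- if (is.character(snp)) match(snp, gm$markers$snp_id) else snp
  if (is.na(j)) stop("unknown SNP id: ", snp)
  g <- gm$genotypes[, j]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("MAF undefined: all genotypes missing at ", snp)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Minor allele frequencies of all SNPs
#'
#' @param gm a [genotype_matrix()].
#' @return Numeric vector of per-SNP MAF (NaN for all-missing columns).
#' @export
maf_vector <- function(gm) {
  f <- allele_freqs(gm)
  pmin(f, 1 - f)
}

#' SNP quality control
#'
#' Removes SNPs with a call rate below `min_call_rate` (strict `<`) or a
#' minor allele frequency below `min_maf` (strict `<`). QC should be run on
#' the designated panel-design sample set, not the full cohort; use
#' [subset_gm()] first.
#'
#' @param gm a [genotype_matrix()] (the design set).
#' @param min_call_rate minimum fraction of non-missing genotypes (default
#'   0.95).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return A list with `gm` (surviving SNPs) and `report`, a data.frame with
#'   snp_id, chromosome, call_rate, maf, excluded, reason, plus a
#'   `per_chromosome` attribute giving percent excluded per chromosome.
#' @export
filter_snps <- function(gm, min_call_rate = 0.95, min_maf = 0.01) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  g <- gm$genotypes
  call_rate <- colMeans(!is.na(g))
  maf <- maf_vector(gm)
  maf[call_rate == 0] <- NA_real_
  reason <- rep(NA_character_, ncol(g))
  reason[!is.na(maf) & maf < min_maf] <- "maf"
  reason[call_rate < min_call_rate] <- "call_rate"
  excluded <- !is.na(reason)
  report <- data.frame(
    snp_id = gm$markers$snp_id,
    chromosome = gm$markers$chromosome,
    call_rate = call_rate,
    maf = maf,
    excluded = excluded,
    reason = reason,
    stringsAsFactors = FALSE
  )
  pc <- vapply(split(excluded, report$chromosome), function(x) 100 * mean(x), 0)
  attr(report, "per_chromosome_pct_excluded") <- pc
  out <- subset_gm(gm, snps = which(!excluded))
  list(gm = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report the report component of [filter_snps()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
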