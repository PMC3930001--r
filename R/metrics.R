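#' Proportion of correctly imputed genotypes
#'
#' @param true_g,imputed_g genotype vectors of equal length; cells with
#'   missing truth are excluded from evaluation.
#' @return Exact-match fraction over evaluated cells.
#' @export
proportion_correct <- function(true_g, imputed_g) {
  if (length(true_g) != length(imputed_g)) stop("vectors differ in length")
  ok <- !is.na(true_g) & !is.na(imputed_g)
  if (!any(ok)) stop("no evaluated cells: proportion correct undefined")
  mean(true_g[ok] == imputed_g[ok])
}

#' Correlation between true and imputed allele counts
#'
#' Pearson correlation of the 0/1/2 codes over evaluated cells. When either
#' vector is constant (e.g. a monomorphic SNP) the correlation is undefined
#' and the SNP is excluded: the function returns `NA` rather than erroring.
#'
#' @param true_g,imputed_g genotype vectors of equal length.
#' @return The correlation in \[-1, 1\], or `NA` (excluded).
#' @export
genotype_correlation <- function(true_g, imputed_g) {
  if (length(true_g) != length(imputed_g)) stop("vectors differ in length")
  ok <- !is.na(true_g) & !is.na(imputed_g)
  if (sum(ok) < 2) return(NA_real_)
  x <- true_g[ok]; y <- imputed_g[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' MAF-adjusted imputation accuracy
#'
#' Rescales a raw proportion-correct by the accuracy expected from random
#' imputation, `(accuracy - random_accuracy) / (1 - random_accuracy)`,
#' removing the chance-concordance floor that inflates raw accuracy at low
#' MAF. May be negative when imputation underperforms chance.
#'
#' @param accuracy observed proportion of correctly imputed genotypes.
#' @param random_accuracy expected proportion under random imputation (from
#'   [expected_random_accuracy()]), in \[0, 1).
#' @return The adjusted accuracy (<= 1), vectorised.
#' @export
adjusted_accuracy <- function(accuracy, random_accuracy) {
  if (any(random_accuracy >= 1)) {
    stop("adjusted accuracy undefined: random accuracy is 1 (monomorphic reference)")
  }
  (accuracy - random_accuracy) / (1 - random_accuracy)
}

#' Per-SNP and per-individual imputation accuracy report
#'
#' Applies the two accuracy measures (proportion correct and allele-count
#' correlation) along both axes of the evaluated cells, attaches the
#' expected random accuracy and the adjusted accuracy per SNP, and
#' summarises each measure as mean (min, max). Constant-vector exclusion is
#' applied to correlations on both axes.
#'
#' @param truth a [genotype_matrix()] holding true genotypes.
#' @param result an `imputation_result`.
#' @param mask logical matrix of cells to evaluate; defaults to
#'   `result$masked`.
#' @param ref_freqs per-SNP allele-b frequency in the reference population
#'   (parameterises the random-accuracy floor).
#' @return A list of class `accuracy_report` with data.frames `per_snp`
#'   (snp_id, n_eval, proportion_correct, correlation, ref_maf,
#'   random_expected, adjusted), `per_individual` (sample_id, n_eval,
#'   proportion_correct, correlation) and `summary`.
#' @export
build_accuracy_report <- function(truth, result, mask = NULL, ref_freqs) {
  if (is.null(mask)) mask <- result$masked
  if (!any(mask)) stop("empty evaluation mask")
  tg <- truth$genotypes
  ig <- result$best_genotype
  stopifnot(identical(dim(tg), dim(ig)))
  eval_ok <- mask & !is.na(tg)
  tg_eval <- ifelse(eval_ok, tg, NA_integer_)
  ig_eval <- ifelse(eval_ok, ig, NA_integer_)

  snp_has <- colSums(eval_ok) > 0
  per_snp <- data.frame(
    snp_id = truth$markers$snp_id,
    n_eval = colSums(eval_ok),
    proportion_correct = NA_real_,
    correlation = NA_real_,
    ref_maf = pmin(ref_freqs, 1 - ref_freqs),
    random_expected = expected_random_accuracy(ref_freqs),
    adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in which(snp_has)) {
    per_snp$proportion_correct[j] <- proportion_correct(tg_eval[, j], ig_eval[, j])
    per_snp$correlation[j] <- genotype_correlation(tg_eval[, j], ig_eval[, j])
  }
  defined <- snp_has & per_snp$random_expected < 1
  per_snp$adjusted[defined] <- adjusted_accuracy(
    per_snp$proportion_correct[defined], per_snp$random_expected[defined])

  ind_has <- rowSums(eval_ok) > 0
  per_ind <- data.frame(
    sample_id = truth$sample_ids,
    n_eval = rowSums(eval_ok),
    proportion_correct = NA_real_,
    correlation = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in which(ind_has)) {
    per_ind$proportion_correct[i] <- proportion_correct(tg_eval[i, ], ig_eval[i, ])
    per_ind$correlation[i] <- genotype_correlation(tg_eval[i, ], ig_eval[i, ])
  }

  summarise <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_))
    c(mean = mean(x), min = min(x), max = max(x))
  }
  summary <- rbind(
    snp_proportion_correct = summarise(per_snp$proportion_correct),
    snp_correlation = summarise(per_snp$correlation),
    snp_adjusted = summarise(per_snp$adjusted),
    individual_proportion_correct = summarise(per_ind$proportion_correct),
    individual_correlation = summarise(per_ind$correlation)
  )
  structure(list(per_snp = per_snp, per_individual = per_ind,
                 summary = as.data.frame(summary), engine = result$engine),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cat("accuracy_report (engine ", x$engine, "):\n", sep = "")
  s <- x$summary
  for (r in rownames(s)) {
    cat(sprintf("  %-32s %.*f (%.*f, %.*f)\n", r,
                digits, s[r, "mean"], digits, s[r, "min"], digits, s[r, "max"]))
  }
  invisible(x)
}

#' Write an accuracy report to disk
#'
#' Two TSVs (`<prefix>.per_snp.tsv`, `<prefix>.per_individual.tsv`) plus a
#' JSON summary (`<prefix>.summary.json`).
#'
#' @param report an `accuracy_report`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_accuracy_report <- function(report, prefix) {
  p1 <- paste0(prefix, ".per_snp.tsv")
  p2 <- paste0(prefix, ".per_individual.tsv")
  p3 <- paste0(prefix, ".summary.json")
  write.table(report$per_snp, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$per_individual, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    c(list(engine = report$engine),
      as.list(as.data.frame(t(report$summary)))),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(per_snp = p1, per_individual = p2, summary = p3))
}
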