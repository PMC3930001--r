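#' Expected accuracy of random genotype imputation
#'
#' Probability that a genotype drawn from Hardy-Weinberg proportions matches
#' an independent draw from the same proportions: `p^4 + 4 p^2 q^2 + q^4`
#' with `q = 1 - p`. This is the chance-concordance floor used to adjust raw
#' imputation accuracies.
#'
#' @param p allele frequency (either allele; the expression is symmetric).
#' @return Expected proportion of correctly imputed genotypes, vectorised.
#' @export
expected_random_accuracy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  p^4 + 4 * p^2 * q^2 + q^4
}

new_imputation_result <- function(posterior, best, engine, seed, masked) {
  structure(list(posterior = posterior, best_genotype = best,
                 engine = engine, seed = seed, masked = masked),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result: engine ", x$engine, ", ",
      sum(x$masked), " imputed cells across ", nrow(x$best_genotype),
      " samples\n", sep = "")
  invisible(x)
}

# argmax over genotype posteriors with ties broken toward the genotype with
# the higher reference (HWE) probability
best_from_posterior <- function(post, ref_freqs) {
  n <- dim(post)[1]; m <- dim(post)[2]
  f <- ref_freqs
  hwe <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  best <- matrix(NA_integer_, n, m)
  for (g in 0:2) {
    pg <- post[, , g + 1, drop = FALSE]
    dim(pg) <- c(n, m)
    is_best <- TRUE
    for (h in 0:2) {
      if (h == g) next
      ph <- post[, , h + 1, drop = FALSE]
      dim(ph) <- c(n, m)
      tie_pref <- matrix(rep(hwe[, g + 1] > hwe[, h + 1] |
                               (hwe[, g + 1] == hwe[, h + 1] & g < h),
                             each = n), n, m)
      is_best <- is_best & (pg > ph | (pg == ph & tie_pref))
    }
    best[is_best] <- g
  }
  best
}

#' Random imputation conditional on reference allele frequencies
#'
#' The baseline engine: each missing genotype is drawn from the
#' Hardy-Weinberg proportions implied by the SNP's allele frequency in the
#' reference population. The recorded posterior is those proportions.
#'
#' @param masked a [genotype_matrix()] with missing cells to impute.
#' @param ref_freqs per-SNP frequency of `allele_b` in the reference
#'   population, aligned with the marker map (e.g. from [allele_freqs()]).
#' @param seed integer seed.
#' @return An `imputation_result` with elements `posterior`
#'   (samples x SNPs x 3 array, `NA` at non-imputed cells), `best_genotype`
#'   (samples x SNPs, drawn genotype at imputed cells), `engine`, `seed`,
#'   `masked` (logical matrix of imputed cells).
#' @export
impute_random <- function(masked, ref_freqs, seed = 1) {
  g <- masked$genotypes
  n <- nrow(g); m <- ncol(g)
  if (length(ref_freqs) != m) stop("ref_freqs must align with the marker map")
  miss <- is.na(g)
  if (any(miss & rep(is.na(ref_freqs), each = n))) {
    stop("missing reference frequency for an imputed SNP")
  }
  f <- matrix(rep(ref_freqs, each = n), n, m)
  p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
  draw <- with_seed(seed, {
    u <- matrix(runif(n * m), n, m)
    ifelse(u < p0, 0L, ifelse(u < p0 + p1, 1L, 2L))
  })
  post <- array(NA_real_, c(n, m, 3))
  best <- matrix(NA_integer_, n, m)
  post[, , 1][miss] <- p0[miss]
  post[, , 2][miss] <- p1[miss]
  post[, , 3][miss] <- p2[miss]
  best[miss] <- draw[miss]
  dimnames(best) <- dimnames(g)
  new_imputation_result(post, best, "random", seed, miss)
}

#' Haplotype-copying HMM imputation
#'
#' Imputes missing genotypes with a diploid Li-Stephens-style hidden Markov
#' model: the hidden state is an ordered pair of template haplotypes from a
#' subsampled reference panel of size `K`; each chromosome of the pair
#' switches templates between adjacent informative sites with probability
#' `1 - exp(-rho * delta)` (`delta` in Morgan, from the marker map's
#' `morgan_position` or bp at 1 cM per Mb); emissions compare the implied
#' genotype with the observed panel genotype under per-allele error rate
#' `err`. Forward-backward messages give posterior genotype triples at all
#' masked sites, with the state posterior transported to each masked site's
#' map position. Chromosomes are processed independently.
#'
#' @param masked a [genotype_matrix()] observed at panel SNPs only.
#' @param reference a phased [genotype_matrix()] (the reference population),
#'   or a 2R x SNPs 0/1 haplotype matrix.
#' @param markers marker map shared by `masked` and the reference; defaults
#'   to `masked$markers`.
#' @param K number of reference haplotypes to subsample as templates
#'   (default 60; capped with a warning when fewer are available).
#' @param err per-allele emission error rate (default 0.002).
#' @param ne effective population size governing the switch rate; the rate
#'   is `rho = 4 * ne / K` per Morgan, so expected template switches per
#'   Morgan scale with population recombination intensity spread over the
#'   K templates.
#' @param seed integer seed (template subsampling).
#' @return An `imputation_result` (engine `"hmm"`), as for
#'   [impute_random()]. On a chromosome where a sample has no observed
#'   genotypes, posteriors fall back to reference Hardy-Weinberg proportions
#'   with a warning.
#' @export
impute_hmm <- function(masked, reference, markers = NULL, K = 60,
                       err = 0.002, ne = 150, seed = 1) {
  if (is.null(markers)) markers <- masked$markers
  H_all <- if (inherits(reference, "genotype_matrix")) {
    if (is.null(reference$phased)) stop("reference must be phased")
    reference$phased
  } else {
    as.matrix(reference)
  }
  if (ncol(H_all) != nrow(markers)) stop("reference haplotypes do not match markers")
  nH <- nrow(H_all)
  if (K > nH) {
    warning("K = ", K, " exceeds available reference haplotypes (", nH,
            "); capping")
    K <- nH
  }
  hsel <- with_seed(seed, sample.int(nH, K))
  H <- H_all[hsel, , drop = FALSE]
  storage.mode(H) <- "integer"

  pos_morgan <- if (!is.null(markers$morgan_position)) {
    markers$morgan_position
  } else {
    markers$bp_position * 1e-8  # 1 cM per Mb proxy
  }
  rho <- 4 * ne / K

  g <- masked$genotypes
  n <- nrow(g); m <- ncol(g)
  post <- array(NA_real_, c(n, m, 3))
  ref_freqs <- colMeans(H_all) # haplotype allele-b frequency
  for (ch in unique(markers$chromosome)) {
    cols <- which(markers$chromosome == ch)
    Gc <- g[, cols, drop = FALSE]
    obs_count <- rowSums(!is.na(Gc))
    no_obs <- obs_count == 0
    if (any(no_obs)) {
      warning("sample(s) with no panel genotypes on chromosome ", ch,
              "; using reference Hardy-Weinberg proportions")
    }
    if (any(!no_obs)) {
      Gi <- Gc[!no_obs, , drop = FALSE]
      Gi[is.na(Gi)] <- -1L
      storage.mode(Gi) <- "integer"
      pp <- .hmm_posterior_cpp(H[, cols, drop = FALSE], Gi,
                               as.numeric(pos_morgan[cols]), rho, err)
      ri <- which(!no_obs)
      for (gg in 1:3) post[ri, cols, gg] <- pp[, , gg]
    }
    if (any(no_obs)) {
      f <- ref_freqs[cols]
      for (i in which(no_obs)) {
        post[i, cols, 1] <- (1 - f)^2
        post[i, cols, 2] <- 2 * f * (1 - f)
        post[i, cols, 3] <- f^2
      }
    }
  }
  miss <- is.na(g)
  # keep posteriors only at imputed cells for the result contract
  for (gg in 1:3) {
    slab <- post[, , gg]
    slab[!miss] <- NA_real_
    post[, , gg] <- slab
  }
  best <- best_from_posterior(post, ref_freqs)
  best[!miss] <- NA_integer_
  dimnames(best) <- dimnames(g)
  new_imputation_result(post, best, "hmm", seed, miss)
}

#' Complete a masked genotype matrix with imputed genotypes
#'
#' @param masked the masked [genotype_matrix()] passed to the engine.
#' @param result an `imputation_result`.
#' @return A `genotype_matrix` with imputed genotypes filled in.
#' @export
apply_imputation <- function(masked, result) {
  g <- masked$genotypes
  g[result$masked] <- result$best_genotype[result$masked]
  genotype_matrix(g, masked$markers, masked$sample_ids)
}

#' Write imputed genotypes and posteriors
#'
#' Writes the completed genotypes as PLINK text plus a posterior TSV with
#' columns sample, snp, p0, p1, p2 (imputed cells only).
#'
#' @param masked the masked [genotype_matrix()].
#' @param result an `imputation_result`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_imputation <- function(masked, result, prefix) {
  paths <- write_plink_text(apply_imputation(masked, result), prefix)
  idx <- which(result$masked, arr.ind = TRUE)
  tsv <- data.frame(
    sample = masked$sample_ids[idx[, 1]],
    snp = masked$markers$snp_id[idx[, 2]],
    p0 = result$posterior[, , 1][result$masked],
    p1 = result$posterior[, , 2][result$masked],
    p2 = result$posterior[, , 3][result$masked]
  )
  ppath <- paste0(prefix, ".posterior.tsv")
  write.table(tsv, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, posterior = ppath))
}

#' Run an external imputation tool through a file adapter
#'
#' Optional bridge to a standalone imputation program: the masked and
#' reference genotypes are written as PLINK text, the configured executable
#' is invoked, and its completed-genotype output (PLINK text, same sample
#' and SNP order) is parsed back into an `imputation_result` with
#' point-mass posteriors. Never required by the rest of the package.
#'
#' @param masked the masked [genotype_matrix()].
#' @param reference the reference [genotype_matrix()].
#' @param adapter list with `command` (path to executable), optional `args`
#'   (character vector; the tokens `{masked}`, `{reference}` and `{out}` are
#'   replaced by the respective file prefixes), and optional `workdir`.
#' @return An `imputation_result` (engine `"external"`).
#' @export
run_external_imputer <- function(masked, reference, adapter) {
  if (is.null(adapter$command) || !file.exists(adapter$command)) {
    stop("external imputer unavailable: ", adapter$command %||% "<unset>")
  }
  wd <- adapter$workdir %||% tempfile("ext_imp_")
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  mpre <- file.path(wd, "masked")
  rpre <- file.path(wd, "reference")
  opre <- file.path(wd, "imputed")
  write_plink_text(masked, mpre)
  write_plink_text(reference, rpre)
  args <- vapply(adapter$args %||% character(0), function(a) {
    a <- gsub("{masked}", mpre, a, fixed = TRUE)
    a <- gsub("{reference}", rpre, a, fixed = TRUE)
    gsub("{out}", opre, a, fixed = TRUE)
  }, "")
  status <- system2(adapter$command, args, stdout = TRUE, stderr = TRUE)
  if (!file.exists(paste0(opre, ".ped"))) {
    stop("external imputer produced no output (", paste0(opre, ".ped"),
         "); log: ", paste(utils::tail(status, 3), collapse = " | "))
  }
  out <- tryCatch(
    read_plink_text(paste0(opre, ".ped"), paste0(opre, ".map")),
    error = function(e) stop("parse error reading external imputer output ",
                             paste0(opre, ".ped"), ": ", conditionMessage(e))
  )
  if (!identical(out$markers$snp_id, masked$markers$snp_id) ||
      !identical(out$sample_ids, masked$sample_ids)) {
    stop("parse error: external imputer output does not match input sample/SNP order")
  }
  miss <- is.na(masked$genotypes)
  n <- nrow(miss); m <- ncol(miss)
  post <- array(NA_real_, c(n, m, 3))
  best <- matrix(NA_integer_, n, m)
  for (gg in 0:2) {
    slab <- matrix(0, n, m)
    slab[out$genotypes == gg] <- 1
    slab[!miss | is.na(out$genotypes)] <- NA_real_
    post[, , gg + 1] <- slab
  }
  best[miss] <- out$genotypes[miss]
  dimnames(best) <- dimnames(masked$genotypes)
  new_imputation_result(post, best, "external", NA_integer_, miss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
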