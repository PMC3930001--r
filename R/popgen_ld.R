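#' Genotypic squared correlation between two SNPs
#'
#' The squared Pearson correlation of 0/1/2 allele counts over jointly
#' non-missing samples (identical to haplotype r^2 under random mating, but
#' computed from genotypes, hence "rg2").
#'
#' @param g1,g2 genotype vectors of equal length.
#' @return A value in \[0, 1\].
#' @export
rg2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("rg2 undefined: fewer than 2 jointly non-missing samples")
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) stop("rg2 undefined: constant genotype vector")
  cor(x, y)^2
}

#' Mean pairwise rg2 in sliding windows
#'
#' For each half-open window `[start, start + window_bp)` advancing by
#' `step_bp` from the chromosome's first SNP, the mean rg2 over all SNP
#' pairs with both members inside. Windows with fewer than 2 usable SNPs are
#' flagged empty (`NA` mean).
#'
#' @param gm a [genotype_matrix()].
#' @param window_bp window width (default 1 Mb).
#' @param step_bp step between window starts (default 0.5 Mb; must be <=
#'   `window_bp`).
#' @return Data.frame: chromosome, window_start, window_end, n_snps,
#'   n_pairs, mean_rg2.
#' @export
sliding_window_mean_rg2 <- function(gm, window_bp = 1000000L,
                                    step_bp = 500000L) {
  if (window_bp < step_bp) stop("window must be at least as wide as the step")
  out <- list()
  for (ch in unique(gm$markers$chromosome)) {
    cols <- which(gm$markers$chromosome == ch)
    bp <- gm$markers$bp_position[cols]
    span <- max(bp) - min(bp)
    n_win <- if (span < window_bp) 1L else floor((span - window_bp) / step_bp) + 1L
    starts <- min(bp) + step_bp * (seq_len(n_win) - 1)
    for (s in starts) {
      inside <- cols[bp >= s & bp < s + window_bp]
      # drop constant SNPs: rg2 undefined for them
      usable <- inside[vapply(inside, function(j) {
        g <- gm$genotypes[, j]
        g <- g[!is.na(g)]
        length(g) >= 2 && var(g) > 0
      }, TRUE)]
      k <- length(usable)
      mean_r <- NA_real_
      npairs <- 0L
      if (k >= 2) {
        vals <- numeric(0)
        for (a in 1:(k - 1)) for (b in (a + 1):k) {
          v <- tryCatch(rg2(gm$genotypes[, usable[a]], gm$genotypes[, usable[b]]),
                        error = function(e) NA_real_)
          vals <- c(vals, v)
        }
        vals <- vals[!is.na(vals)]
        npairs <- length(vals)
        if (npairs) mean_r <- mean(vals)
      }
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch, window_start = s, window_end = s + window_bp,
        n_snps = k, n_pairs = npairs, mean_rg2 = mean_r,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mean genomic relationship between two sample groups
#'
#' Builds an allele-frequency-centred genomic relationship matrix
#' (VanRaden's first construction: centred genotypes `Z = G - 2p`, GRM =
#' `Z Z' / (2 * sum p (1 - p))`) and returns the mean over the off-diagonal
#' (a, b) pairs.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b character vectors of sample ids (may overlap; the
#'   diagonal is always excluded).
#' @return Mean relationship between the groups.
#' @export
mean_genomic_relationship <- function(gm, group_a, group_b) {
  ia <- match(group_a, gm$sample_ids)
  ib <- match(group_b, gm$sample_ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id(s)")
  G <- gm$genotypes
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs for relationship computation")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  grm <- tcrossprod(Z) / denom
  vals <- grm[ia, ib, drop = FALSE]
  same <- outer(ia, ib, "==")
  vals <- vals[!same]
  if (!length(vals)) stop("no off-diagonal pairs between the groups")
  mean(vals)
}
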