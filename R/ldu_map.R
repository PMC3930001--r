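#' Two-locus haplotype frequency estimation by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased genotypes, resolving double-heterozygote phase by
#' expectation-maximisation. Alleles are labelled 0 (`allele_a`) and 1
#' (`allele_b`), matching the 0/1/2 genotype coding.
#'
#' @param g1,g2 integer genotype vectors (0/1/2, `NA` allowed) of equal
#'   length.
#' @param tol convergence tolerance on the frequency vector.
#' @param max_iter maximum EM iterations.
#' @return Named numeric vector `c("00","01","10","11")` of haplotype
#'   frequencies summing to 1 (first digit = allele at locus 1).
#' @export
estimate_two_locus_haplotype_freqs <- function(g1, g2, tol = 1e-10,
                                               max_iter = 500) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) == 0) stop("no jointly non-missing samples")
  p1 <- sum(g1) / (2 * length(g1))
  p2 <- sum(g2) / (2 * length(g2))
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("degenerate input: monomorphic locus among jointly non-missing samples")
  }
  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  N2 <- 2 * length(g1)
  # fixed haplotype contributions from all unambiguous genotype pairs
  base <- c(
    `00` = 2 * n[1, 1] + n[1, 2] + n[2, 1],
    `01` = 2 * n[1, 3] + n[1, 2] + n[2, 3],
    `10` = 2 * n[3, 1] + n[2, 1] + n[3, 2],
    `11` = 2 * n[3, 3] + n[3, 2] + n[2, 3]
  )
  ndh <- n[2, 2]
  f <- c(`00` = (1 - p1) * (1 - p2), `01` = (1 - p1) * p2,
         `10` = p1 * (1 - p2), `11` = p1 * p2)
  for (it in seq_len(max_iter)) {
    num <- f["00"] * f["11"]
    den <- num + f["01"] * f["10"]
    w <- if (den > 0) num / den else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    fnew <- cnt / N2
    if (max(abs(fnew - f)) < tol) {
      f <- fnew
      break
    }
    f <- fnew
  }
  f
}

#' Lewontin's D-prime from haplotype frequencies
#'
#' @param hap_freqs numeric vector of four haplotype frequencies in the order
#'   `(00, 01, 10, 11)` (first digit = allele at locus 1), summing to 1.
#' @return |D| / D_max in \[0, 1\].
#' @export
dprime <- function(hap_freqs) {
  f <- as.numeric(hap_freqs)
  if (abs(sum(f) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  p1 <- f[3] + f[4]
  p2 <- f[2] + f[4]
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("D' undefined: boundary marginal allele frequency")
  }
  D <- f[4] - p1 * p2
  dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
          else min(p1 * p2, (1 - p1) * (1 - p2))
  if (dmax <= 0) return(0)
  min(abs(D) / dmax, 1)
}

#' Malecot association prediction at an LDU distance
#'
#' The Malecot model predicts association declining with distance as
#' `(1 - L) * M * exp(-eps * d) + L`. With distance expressed in LD units the
#' decline rate is absorbed into the coordinate, so the prediction is
#' `(1 - L) * M * exp(-delta_ldu) + L`.
#'
#' @param delta_ldu non-negative distance(s) in LD units.
#' @param M intercept at zero distance, in (0, 1].
#' @param L asymptotic association at large distance, in \[0, 1).
#' @return Predicted association value(s).
#' @export
malecot_predicted_association <- function(delta_ldu, M, L) {
  (1 - L) * M * exp(-delta_ldu) + L
}

#' Build a linkage-disequilibrium-unit map for one chromosome
#'
#' Constructs an additive LDU coordinate from unphased genotypes: |D'| is
#' computed by two-locus EM for all SNP pairs within `max_pair_bp`; the
#' Malecot asymptote `L` is estimated as the mean |D'| among the most
#' distant pairs on the chromosome (which approximate unlinked background
#' association, including its finite-sample floor) and the intercept `M` is
#' fixed;
#' per-interval decline rates `eps >= 0` are then fitted by coordinate
#' descent, minimising the sum of squared differences between predicted and
#' observed |D'|, where a pair's predicted association uses the summed
#' `eps_i * d_i` over the base-pair intervals it spans. LDU positions are the
#' cumulative `eps_i * d_i`.
#'
#' @param gm a [genotype_matrix()] (typically the panel-design sample set).
#' @param chromosome chromosome to map; may be omitted when `gm` holds one.
#' @param max_pair_bp maximum pair distance in bp (default 500 kb).
#' @param M Malecot intercept (default 1, single-origin assumption).
#' @param L Malecot asymptote; `NULL` (default) estimates it from the data.
#' @param max_sweeps maximum coordinate-descent sweeps over intervals.
#' @param tol relative objective-change convergence tolerance.
#' @param max_interval_ldu upper bound on the LDU length of one interval.
#' @return A list of class `ldu_map`: `chromosome`, `snp_ids`,
#'   `bp_positions`, `ldu_positions` (starting at 0, non-decreasing),
#'   `epsilons` (per-bp decline rate per interval), `fit_params` (M, L),
#'   `n_pairs`, `n_skipped`, `objective`, `converged`.
#' @export
build_ldu_map <- function(gm, chromosome = NULL, max_pair_bp = 500000L,
                          M = 1, L = NULL, max_sweeps = 60, tol = 1e-5,
                          max_interval_ldu = 10) {
  chroms <- unique(gm$markers$chromosome)
  if (is.null(chromosome)) {
    if (length(chroms) > 1) stop("gm has multiple chromosomes; pass `chromosome`")
    chromosome <- chroms[1]
  }
  sel <- which(gm$markers$chromosome == chromosome)
  if (length(sel) < 3) stop("need >= 3 SNPs on chromosome ", chromosome)
  sub <- subset_gm(gm, snps = sel)
  maf <- maf_vector(sub)
  poly <- which(!is.na(maf) & maf > 0)
  if (length(poly) < 3) stop("need >= 3 polymorphic SNPs on chromosome ", chromosome)
  sub <- subset_gm(sub, snps = poly)
  bp <- sub$markers$bp_position
  m <- length(bp)
  G <- sub$genotypes

  # admissible pairs and their |D'|
  pj <- integer(0); pk <- integer(0)
  for (j in seq_len(m - 1)) {
    kmax <- j + findInterval(bp[j] + max_pair_bp, bp[(j + 1):m])
    if (kmax > j) {
      pj <- c(pj, rep.int(j, kmax - j))
      pk <- c(pk, (j + 1):kmax)
    }
  }
  np <- length(pj)
  if (np == 0) stop("no SNP pairs within max_pair_bp")
  dp <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    dp[p] <- tryCatch(
      dprime(estimate_two_locus_haplotype_freqs(G[, pj[p]], G[, pk[p]])),
      error = function(e) NA_real_
    )
  }
  keep <- !is.na(dp)
  n_skipped <- sum(!keep)
  pj <- pj[keep]; pk <- pk[keep]; dp <- dp[keep]
  np <- length(dp)
  if (np == 0) stop("no pairs with defined D'")
  dist_bp <- bp[pk] - bp[pj]

  if (is.null(L)) {
    # background association from the most distant pairs available: offset
    # ~70% of the map, up to 200 pairs; fall back to the window's top
    # distance decile on very short maps
    offs <- max(1L, as.integer(round(0.7 * m)))
    js <- unique(as.integer(round(seq(1, m - offs, length.out = min(200, m - offs)))))
    far <- vapply(js, function(j) {
      tryCatch(dprime(estimate_two_locus_haplotype_freqs(G[, j], G[, j + offs])),
               error = function(e) NA_real_)
    }, 0)
    far <- far[!is.na(far)]
    L <- if (length(far) >= 10) mean(far) else {
      thr <- quantile(dist_bp, 0.9, names = FALSE)
      mean(dp[dist_bp >= thr])
    }
    L <- max(0, min(L, 0.95))
  }

  d_int <- diff(bp)  # interval lengths, bp
  # initialise eps by inverting the Malecot prediction on adjacent pairs
  adj <- which(pk == pj + 1)
  ldu_len0 <- rep(NA_real_, m - 1)
  inv_ldu <- function(y) {
    z <- (y - L) / ((1 - L) * M)
    z <- max(z, exp(-max_interval_ldu))
    z <- min(z, 1)
    -log(z)
  }
  ldu_len0[pj[adj]] <- vapply(dp[adj], inv_ldu, 0)
  fill <- stats::median(ldu_len0, na.rm = TRUE)
  if (is.na(fill)) fill <- 0.1
  ldu_len0[is.na(ldu_len0)] <- fill
  eps <- ldu_len0 / d_int

  # pair -> spanned intervals bookkeeping
  delta <- vapply(seq_len(np), function(p) {
    sum(eps[pj[p]:(pk[p] - 1)] * d_int[pj[p]:(pk[p] - 1)])
  }, 0)
  span_pairs <- vector("list", m - 1)
  for (p in seq_len(np)) {
    for (i in pj[p]:(pk[p] - 1)) span_pairs[[i]] <- c(span_pairs[[i]], p)
  }
  objective <- sum((malecot_predicted_association(delta, M, L) - dp)^2)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (i in seq_len(m - 1)) {
      ps <- span_pairs[[i]]
      if (is.null(ps)) { eps[i] <- 0; next }
      a <- delta[ps] - eps[i] * d_int[i]
      y <- dp[ps]
      # optimise the interval's LDU length directly so the search tolerance
      # is scale-free in map units
      h <- function(dl) {
        sum((malecot_predicted_association(a + dl, M, L) - y)^2)
      }
      opt <- optimize(h, interval = c(0, max_interval_ldu), tol = 1e-8)
      # boundary check: optimize() never evaluates the endpoints themselves
      if (h(0) <= opt$objective) opt <- list(minimum = 0, objective = h(0))
      delta[ps] <- a + opt$minimum
      eps[i] <- opt$minimum / d_int[i]
    }
    obj_new <- sum((malecot_predicted_association(delta, M, L) - dp)^2)
    if (objective - obj_new <= tol * max(objective, 1e-12)) {
      objective <- obj_new
      converged <- TRUE
      break
    }
    objective <- obj_new
  }
  if (!converged) {
    warning("LDU map fit did not converge in ", max_sweeps,
            " sweeps; returning best map so far")
  }
  ldu <- c(0, cumsum(eps * d_int))
  structure(list(
    chromosome = chromosome,
    snp_ids = sub$markers$snp_id,
    bp_positions = bp,
    ldu_positions = ldu,
    epsilons = eps,
    fit_params = list(M = M, L = L),
    n_pairs = np,
    n_skipped = n_skipped,
    objective = objective,
    converged = converged
  ), class = "ldu_map")
}

#' @export
print.ldu_map <- function(x, ...) {
  cat("ldu_map: chromosome ", x$chromosome, ", ", length(x$snp_ids),
      " SNPs, span ", round(max(x$ldu_positions), 2), " LDU over ",
      round(diff(range(x$bp_positions)) / 1e6, 2), " Mb (M=",
      x$fit_params$M, ", L=", round(x$fit_params$L, 3), ")\n", sep = "")
  invisible(x)
}

#' Write an LDU map as TSV
#'
#' @param map an `ldu_map`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ldu_map <- function(map, path) {
  write.table(
    data.frame(snp_id = map$snp_ids, chromosome = map$chromosome,
               bp = map$bp_positions, ldu = map$ldu_positions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot LDU versus physical position
#'
#' @param x an `ldu_map`.
#' @param ... passed to [plot()].
#' @export
plot.ldu_map <- function(x, ...) {
  plot(x$bp_positions / 1e6, x$ldu_positions, type = "s",
       xlab = "Position (Mb)", ylab = "LDU",
       main = paste("LD map, chromosome", x$chromosome), ...)
  invisible(x)
}
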