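# Shared fixtures, memoised so expensive simulated populations are built
# once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small deterministic genotype matrix for unit tests
toy_gm <- function(genotypes, bp = NULL, chromosome = "1") {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  mk <- marker_map(sprintf("snp%02d", seq_len(m)), chromosome, bp)
  genotype_matrix(genotypes, mk)
}

# moderate uniform-recombination population: 0.5 Morgan, ~300 SNPs, 500
# samples (enough for LD-structure and imputation checks at test speed)
pop_small <- function() {
  fixture("pop_small", function() {
    simulate_population(sim_config(chrom_morgans = 0.5,
                                   snp_density_per_morgan = 600,
                                   n_samples = 500, seed = 77))
  })
}

# large-Ne, no-bottleneck population: the LD landscape along the chromosome
# is smooth, isolating map-construction behaviour from the genealogical
# lumpiness that strong-drift demographies genuinely produce
pop_smooth <- function() {
  fixture("pop_smooth", function() {
    simulate_population(sim_config(ne = 400, founder_pool = 400,
                                   chrom_morgans = 0.5,
                                   snp_density_per_morgan = 600,
                                   n_samples = 500, seed = 88))
  })
}

# the same population pre-split and QC'd, with design-set MAFs
pop_small_parts <- function() {
  fixture("pop_small_parts", function() {
    pop <- pop_small()
    sp <- split_samples(pop$sample_ids, c(A = 150, B = 0.75, C = 0.25),
                        seed = 77)
    A <- subset_gm(pop, samples = sp$sets$A)
    qc <- filter_snps(A)
    popq <- subset_gm(pop, snps = qc$gm$markers$snp_id)
    list(pop = popq,
         mafs = maf_vector(subset_gm(popq, samples = sp$sets$A)),
         split = sp,
         B = subset_gm(popq, samples = sp$sets$B),
         C = subset_gm(popq, samples = sp$sets$C))
  })
}

# dense-matrix reference implementation of the diploid haplotype-copying
# forward-backward, used as an independent oracle at tiny K
hmm_oracle_posteriors <- function(H, g_obs, pos, rho, err) {
  K <- nrow(H); m <- ncol(H)
  Emat <- function(e) {
    c_ <- 1 - e
    rbind(c(c_^2, 2 * c_ * e, e^2),
          c(c_ * e, c_^2 + e^2, c_ * e),
          c(e^2, 2 * c_ * e, c_^2))
  }
  E3 <- Emat(err)
  kern1 <- function(s) (1 - s) * diag(K) + s / K * matrix(1, K, K)
  kern2 <- function(s) kronecker(kern1(s), kern1(s))  # state q = k1 + K*k2
  imp_at <- function(j) as.vector(outer(H[, j], H[, j], "+")) # k1 varies fastest
  emis <- function(j, g) E3[imp_at(j) + 1, g + 1]
  inf <- which(!is.na(g_obs))
  ni <- length(inf)
  KK <- K * K
  alpha <- matrix(0, KK, ni)
  a <- rep(1 / KK, KK)
  for (t in seq_len(ni)) {
    if (t > 1) {
      s <- 1 - exp(-rho * (pos[inf[t]] - pos[inf[t - 1]]))
      a <- as.vector(t(kern2(s)) %*% a)
    }
    a <- a * emis(inf[t], g_obs[inf[t]])
    a <- a / sum(a)
    alpha[, t] <- a
  }
  betaN <- matrix(0, KK, ni)
  b <- rep(1, KK)
  betaN[, ni] <- b
  if (ni > 1) {
    for (t in (ni - 1):1) {
      s <- 1 - exp(-rho * (pos[inf[t + 1]] - pos[inf[t]]))
      be <- b * emis(inf[t + 1], g_obs[inf[t + 1]])
      b <- as.vector(kern2(s) %*% be)
      b <- b / sum(b)
      betaN[, t] <- b
    }
  }
  post <- matrix(0, m, 3)
  for (j in seq_len(m)) {
    left <- max(c(0, which(inf <= j)))
    if (left > 0 && inf[left] == j) {
      w <- alpha[, left] * betaN[, left]
    } else if (left == 0) {
      sR <- 1 - exp(-rho * (pos[inf[1]] - pos[j]))
      be <- betaN[, 1] * emis(inf[1], g_obs[inf[1]])
      w <- as.vector(kern2(sR) %*% be)
    } else if (left == ni) {
      sL <- 1 - exp(-rho * (pos[j] - pos[inf[left]]))
      w <- as.vector(t(kern2(sL)) %*% alpha[, left])
    } else {
      sL <- 1 - exp(-rho * (pos[j] - pos[inf[left]]))
      f <- as.vector(t(kern2(sL)) %*% alpha[, left])
      sR <- 1 - exp(-rho * (pos[inf[left + 1]] - pos[j]))
      be <- betaN[, left + 1] * emis(inf[left + 1], g_obs[inf[left + 1]])
      bb <- as.vector(kern2(sR) %*% be)
      w <- f * bb
    }
    w <- w / sum(w)
    imp <- imp_at(j)
    for (g in 0:2) post[j, g + 1] <- sum(w[imp == g])
  }
  post
}
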