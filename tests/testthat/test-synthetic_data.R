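test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(chrom_morgans = 0.2, snp_density_per_morgan = 300,
                    n_samples = 80, burn_in_generations = 50, seed = 31)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$markers, p2$markers)
  cfg2 <- sim_config(chrom_morgans = 0.2, snp_density_per_morgan = 300,
                     n_samples = 80, burn_in_generations = 50, seed = 32)
  p3 <- simulate_population(cfg2)
  expect_false(identical(p1$genotypes, p3$genotypes))
})

test_that("truth phase is consistent with genotypes and coordinates valid", {
  pop <- pop_small()
  n <- length(pop$sample_ids)
  gsum <- pop$phased[seq(1, 2 * n, 2), ] + pop$phased[seq(2, 2 * n, 2), ]
  expect_identical(unname(gsum), unname(pop$genotypes))
  expect_false(is.unsorted(pop$markers$bp_position))
  expect_false(is.unsorted(pop$markers$morgan_position))
})

test_that("the ascertained MAF spectrum is chip-like", {
  pop <- pop_small()
  maf <- maf_vector(pop)
  expect_true(all(maf >= 0.05 - 1e-9))
  expect_gt(mean(maf), 0.15)
  expect_lt(mean(maf), 0.30)
})

test_that("random mating leaves genotypes near Hardy-Weinberg equilibrium", {
  pop <- pop_small()
  g <- pop$genotypes
  n <- nrow(g)
  chi2 <- apply(g, 2, function(x) {
    p <- mean(x) / 2
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- tabulate(x + 1L, 3)
    sum((o - e)^2 / pmax(e, 1e-9))
  })
  # one degree of freedom: mean chi-square should sit near 1, not inflated
  expect_lt(mean(chi2), 1.5)
})

test_that("without recombination the chromosome is one LD block", {
  cfg <- sim_config(chrom_morgans = 0, snp_density_per_morgan = 400,
                    n_samples = 200, seed = 41)
  pop <- simulate_population(cfg)
  g <- pop$genotypes
  set.seed(41)
  vals <- c()
  for (rep in 1:300) {
    jk <- sample(ncol(g), 2)
    v <- tryCatch(rg2(g[, jk[1]], g[, jk[2]]), error = function(e) NA_real_)
    vals <- c(vals, v)
  }
  expect_gt(median(vals, na.rm = TRUE), 0.5)
})

test_that("binned r2 decay is consistent with the Sved expectation", {
  pop <- pop_small()  # Ne = 150, uniform recombination
  mk <- pop$markers
  g <- pop$genotypes
  set.seed(42)
  r2 <- c(); d <- c()
  idx <- sort(sample(nrow(mk), 200))
  for (a in seq_along(idx)) for (off in c(6, 12, 24, 48)) {
    k <- idx[a] + off
    if (k <= nrow(mk)) {
      v <- tryCatch(rg2(g[, idx[a]], g[, k]), error = function(e) NA_real_)
      r2 <- c(r2, v)
      d <- c(d, mk$morgan_position[k] - mk$morgan_position[idx[a]])
    }
  }
  ok <- !is.na(r2) & d >= 0.01 & d <= 0.1
  bins <- cut(d[ok], breaks = c(0.01, 0.025, 0.05, 0.1))
  obs <- tapply(r2[ok], bins, mean)
  mid <- tapply(d[ok], bins, mean)
  sved <- 1 / (1 + 4 * 150 * mid)
  expect_true(all(abs(obs - sved) / sved < 0.5))
})

test_that("population splits diverge with time and mix with migration", {
  base <- function(split, mig, seed) {
    sim_config(chrom_morgans = 0.2, snp_density_per_morgan = 300,
               n_samples = 150, burn_in_generations = 100,
               generations_since_founding = max(30, split),
               split_generations = split, migration_rate = mig, seed = seed)
  }
  none <- simulate_split_populations(base(0, 0, 51))
  expect_gt(none$freq_correlation, 0.95)
  recent <- simulate_split_populations(base(5, 0.05, 51))
  expect_gte(recent$freq_correlation, 0.9)
  deep <- simulate_split_populations(base(100, 0, 51))
  expect_lt(deep$freq_correlation, recent$freq_correlation)
})

test_that("half-sib construction is seeded, pedigreed, and optional", {
  pop <- pop_small()
  f1 <- add_half_sib_structure(pop, list(n = 2, size = 5), seed = 61)
  f2 <- add_half_sib_structure(pop, list(n = 2, size = 5), seed = 61)
  expect_identical(f1$genotypes, f2$genotypes)
  expect_equal(length(f1$sample_ids), length(pop$sample_ids) + 10)
  ped <- attr(f1, "pedigree")
  expect_equal(nrow(ped), 10)
  expect_equal(length(unique(ped$sire)), 2)
  expect_identical(add_half_sib_structure(pop, list(n = 0), seed = 1), pop)
  expect_error(add_half_sib_structure(pop, list(n = 1, size = 0), seed = 1),
               "family size")
})

test_that("infeasible SNP density is reported with a remedy", {
  cfg <- sim_config(ne = 30, chrom_morgans = 0.05, snp_density_per_morgan = 5000,
                    founder_pool = 3, n_samples = 50,
                    burn_in_generations = 400, seed = 71)
  expect_error(simulate_population(cfg), "founder_pool")
})
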