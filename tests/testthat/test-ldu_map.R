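test_that("two-locus EM recovers hand-resolvable haplotype frequencies", {
  # identical loci with only opposite homozygotes: phase is unambiguous
  g <- c(0, 0, 2, 2, 0, 2)
  f <- estimate_two_locus_haplotype_freqs(g, g)
  expect_equal(unname(f["00"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(f["11"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(f["01"] + f["10"]), 0, tolerance = 1e-8)
  expect_equal(dprime(f), 1)
})

test_that("EM marginals match observed allele frequencies and sum to 1", {
  set.seed(9)
  for (rep in 1:10) {
    g1 <- rbinom(80, 2, runif(1, 0.2, 0.8))
    g2 <- rbinom(80, 2, runif(1, 0.2, 0.8))
    if (var(g1) == 0 || var(g2) == 0) next
    f <- estimate_two_locus_haplotype_freqs(g1, g2)
    expect_equal(sum(f), 1, tolerance = 1e-8)
    expect_equal(unname(f["10"] + f["11"]), mean(g1) / 2, tolerance = 1e-8)
    expect_equal(unname(f["01"] + f["11"]), mean(g2) / 2, tolerance = 1e-8)
  }
})

test_that("independently shuffled loci show near-zero |D'|", {
  set.seed(11)
  g1 <- rbinom(500, 2, 0.4)
  g2 <- sample(g1)
  f <- estimate_two_locus_haplotype_freqs(g1, g2)
  expect_lt(dprime(f), 0.15)
})

test_that("EM rejects monomorphic input", {
  expect_error(estimate_two_locus_haplotype_freqs(rep(0, 10), rbinom(10, 2, .5)),
               "monomorphic")
})

test_that("D' follows the Lewontin normalisation", {
  expect_equal(dprime(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(dprime(c(0.5, 0, 0, 0.5)), 1)
  # D = 0.3 - 0.5*0.4 = 0.1; Dmax = min(0.5*0.6, 0.5*0.4) = 0.2
  expect_equal(dprime(c(0.4, 0.1, 0.2, 0.3)), 0.5)
  expect_error(dprime(c(0.5, 0.5, 0, 0)), "boundary")
})

test_that("the Malecot prediction has the right intercept, asymptote, decay", {
  expect_equal(malecot_predicted_association(0, M = 1, L = 0), 1)
  expect_equal(malecot_predicted_association(50, M = 1, L = 0.1), 0.1,
               tolerance = 1e-8)
  expect_equal(malecot_predicted_association(1, M = 1, L = 0), exp(-1))
})

make_block_pop <- function(n = 200, block_sizes = c(10, 10), spacing = 1e4,
                           seed = 4) {
  # blocks of complete internal LD, independent across blocks
  set.seed(seed)
  m <- sum(block_sizes)
  nh <- 2 * n
  hap <- matrix(0L, nh, m)
  col <- 0
  for (b in seq_along(block_sizes)) {
    allele <- rbinom(nh, 1, 0.5)
    for (j in seq_len(block_sizes[b])) {
      col <- col + 1
      hap[, col] <- allele
    }
  }
  g <- hap[seq(1, nh, 2), ] + hap[seq(2, nh, 2), ]
  toy_gm(g, bp = seq_len(m) * spacing)
}

test_that("a recombination hotspot absorbs most of the LDU span", {
  gm <- make_block_pop()
  map <- build_ldu_map(gm, max_pair_bp = 200000L)
  span <- max(map$ldu_positions)
  hot <- map$ldu_positions[11] - map$ldu_positions[10]  # between the blocks
  expect_gt(span, 0)
  expect_gt(hot / span, 0.8)
  expect_true(all(diff(map$ldu_positions) >= 0))
})

test_that("complete-LD regions collapse to near-zero LDU span", {
  gm <- make_block_pop(block_sizes = c(20))
  map <- build_ldu_map(gm, max_pair_bp = 200000L)
  expect_lt(max(map$ldu_positions), 0.5)
})

test_that("LDU accumulates near-linearly under uniform recombination", {
  map <- build_ldu_map(pop_smooth())
  fit <- summary(lm(map$ldu_positions ~ map$bp_positions))
  expect_gt(fit$r.squared, 0.9)
  expect_true(all(diff(map$ldu_positions) >= -1e-12))
})

test_that("total LDU span is invariant to uniform bp rescaling", {
  parts <- pop_small_parts()
  A <- subset_gm(parts$pop, samples = parts$split$sets$A)
  map1 <- build_ldu_map(A)
  mk2 <- A$markers
  gm2 <- genotype_matrix(A$genotypes,
                         marker_map(mk2$snp_id, mk2$chromosome,
                                    mk2$bp_position * 10L),
                         A$sample_ids)
  map2 <- build_ldu_map(gm2, max_pair_bp = 5000000L)
  expect_equal(max(map2$ldu_positions), max(map1$ldu_positions),
               tolerance = 1e-6)
})

test_that("LDU map construction needs enough polymorphic SNPs", {
  gm <- toy_gm(matrix(0L, 10, 4))
  expect_error(build_ldu_map(gm), "polymorphic")
})
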