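test_that("expected random accuracy follows p^4 + 4p^2q^2 + q^4", {
  expect_equal(expected_random_accuracy(1), 1)
  expect_equal(expected_random_accuracy(0.5), 0.375)
  expect_equal(expected_random_accuracy(0.9), 0.6886, tolerance = 1e-10)
  expect_equal(expected_random_accuracy(0.3), expected_random_accuracy(0.7))
})

test_that("random imputation is degenerate at fixed alleles and seeded", {
  gm <- toy_gm(matrix(NA_integer_, 20, 3))
  res0 <- impute_random(gm, ref_freqs = c(0, 0, 0), seed = 1)
  expect_true(all(res0$best_genotype == 0))
  res2 <- impute_random(gm, ref_freqs = c(1, 1, 1), seed = 1)
  expect_true(all(res2$best_genotype == 2))
  resa <- impute_random(gm, ref_freqs = c(0.5, 0.2, 0.8), seed = 9)
  resb <- impute_random(gm, ref_freqs = c(0.5, 0.2, 0.8), seed = 9)
  expect_identical(resa$best_genotype, resb$best_genotype)
  expect_error(impute_random(gm, ref_freqs = c(0.5, NA, 0.5), seed = 1),
               "missing reference frequency")
})

test_that("random draws follow Hardy-Weinberg proportions", {
  gm <- toy_gm(matrix(NA_integer_, 10000, 1))
  res <- impute_random(gm, ref_freqs = 0.5, seed = 3)
  tab <- tabulate(res$best_genotype + 1L, 3) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) < 3 * se))
  # posterior records the proportions and sums to one
  expect_equal(unname(res$posterior[1, 1, ]), c(0.25, 0.5, 0.25))
})

test_that("a single reference pair is copied through at masked sites", {
  set.seed(4)
  m <- 12
  h1 <- rbinom(m, 1, 0.5)
  h2 <- rbinom(m, 1, 0.5)
  h1[c(3, 8)] <- c(0, 1); h2[c(3, 8)] <- c(0, 0)  # panel sites distinguish
  mk <- marker_map(sprintf("s%02d", 1:m), "1", seq_len(m) * 1e5)
  ref <- genotype_matrix(matrix(h1 + h2, 1), mk, "R1",
                         phased = rbind(h1, h2))
  g_obs <- rep(NA_integer_, m)
  g_obs[c(3, 8)] <- (h1 + h2)[c(3, 8)]
  masked <- genotype_matrix(matrix(g_obs, 1), mk, "T1")
  expect_warning(res <- impute_hmm(masked, ref, K = 2, err = 1e-6, seed = 1),
                 NA)  # K equals available haplotypes: no capping warning
  expect_equal(unname(res$best_genotype[1, res$masked[1, ]]),
               (h1 + h2)[is.na(g_obs)])
  expect_warning(impute_hmm(masked, ref, K = 10, err = 1e-6, seed = 1),
                 "capping")
})

test_that("HMM posteriors match a dense-matrix forward-backward oracle", {
  set.seed(6)
  K <- 4; m <- 9
  H <- matrix(rbinom(K * m, 1, 0.5), K, m)
  mk <- marker_map(sprintf("s%02d", 1:m), "1", seq_len(m) * 2e5)
  g_obs <- rep(NA_integer_, m)
  g_obs[c(2, 5, 9)] <- c(H[1, 2] + H[2, 2], H[1, 5] + H[2, 5], 1L)
  masked <- genotype_matrix(matrix(g_obs, 1), mk, "T1")
  rho <- 4 * 150 / K
  res <- impute_hmm(masked, H, markers = mk, K = K, err = 0.01, ne = 150,
                    seed = 1)
  oracle <- hmm_oracle_posteriors(H, g_obs, mk$bp_position * 1e-8, rho, 0.01)
  for (j in which(is.na(g_obs))) {
    expect_equal(unname(res$posterior[1, j, ]), oracle[j, ], tolerance = 1e-6)
  }
})

test_that("complete LD with an adjacent panel SNP pins the posterior", {
  # two reference haplotypes, masked SNP a perfect proxy of its neighbour
  H <- rbind(c(1, 1, 1), c(0, 0, 0))
  mk <- marker_map(c("a", "b", "c"), "1", c(1e4, 2e4, 3e4))
  masked <- genotype_matrix(matrix(c(2L, NA, 2L), 1), mk, "T1")
  res <- impute_hmm(masked, H, markers = mk, K = 2, err = 0.002, ne = 15,
                    seed = 1)
  expect_gt(res$posterior[1, 2, 3], 0.99)
  expect_equal(unname(res$best_genotype[1, 2]), 2L)
  # posteriors normalise at every imputed cell
  expect_equal(sum(res$posterior[1, 2, ]), 1, tolerance = 1e-9)
})

test_that("the HMM beats the random baseline on simulated data", {
  parts <- pop_small_parts()
  pan <- design_panel(parts$pop$markers, parts$mafs, "bpeq", 18, seed = 5)
  masked <- mask_to_panel(parts$C, pan)
  fB <- allele_freqs(parts$B)
  hmm <- impute_hmm(masked, parts$B, K = 60, seed = 5)
  rnd <- impute_random(masked, fB, seed = 5)
  truth <- parts$C$genotypes
  acc_hmm <- mean(truth[hmm$masked] == hmm$best_genotype[hmm$masked])
  acc_rnd <- mean(truth[rnd$masked] == rnd$best_genotype[rnd$masked])
  expect_gt(acc_hmm, acc_rnd)
})

test_that("a sample with no panel genotypes falls back to HWE with warning", {
  H <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  mk <- marker_map(c("a", "b", "c"), "1", c(1e5, 2e5, 3e5))
  masked <- genotype_matrix(matrix(NA_integer_, 1, 3), mk, "T1")
  expect_warning(res <- impute_hmm(masked, H, markers = mk, K = 4, seed = 1),
                 "no panel genotypes")
  f <- colMeans(H)
  expect_equal(unname(res$posterior[1, , 1]), (1 - f)^2)
})

test_that("the external-imputer adapter round-trips through a mock tool", {
  dir <- withr::local_tempdir()
  tool <- file.path(dir, "mock_imputer.sh")
  writeLines(c("#!/bin/sh",
               "cp \"$1.ped\" \"$3.ped\"",
               "cp \"$1.map\" \"$3.map\"",
               "cp \"$1.ref\" \"$3.ref\""), tool)
  Sys.chmod(tool, "0755")
  set.seed(12)
  gm <- toy_gm(matrix(sample(0:2, 40, TRUE), 4, 10))
  gm$genotypes[1, 3] <- NA_integer_
  ref <- toy_gm(matrix(sample(0:2, 40, TRUE), 4, 10))
  res <- run_external_imputer(gm, ref, list(command = tool,
                                            args = c("{masked}", "{reference}",
                                                     "{out}")))
  expect_equal(res$engine, "external")
  # the identity tool returns the observed genotypes unchanged; the one
  # masked cell stays missing in its output
  expect_true(is.na(res$best_genotype[1, 3]))
  # a tool that emits garbage triggers a parse error
  bad <- file.path(dir, "bad_imputer.sh")
  writeLines(c("#!/bin/sh", "echo garbage > \"$3.ped\"",
               "echo junk > \"$3.map\""), bad)
  Sys.chmod(bad, "0755")
  expect_error(run_external_imputer(gm, ref, list(command = bad,
                                                  args = c("{masked}", "{reference}", "{out}"))),
               "parse error")
  expect_error(run_external_imputer(gm, ref, list(command = "/nonexistent")),
               "unavailable")
})
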