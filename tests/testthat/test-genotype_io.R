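test_that("PLINK text genotypes are recoded to allele counts", {
  dir <- withr::local_tempdir()
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "toy.map"))
  writeLines(c("FAM S1 0 0 0 -9 A A A G",
               "FAM S2 0 0 0 -9 A A G G"),
             file.path(dir, "toy.ped"))
  gm <- read_plink_text(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))
  # rs2: G is the major allele (3 of 4), so genotypes count copies of A
  expect_equal(unname(gm$genotypes["S1", ]), c(0L, 1L))
  expect_equal(unname(gm$genotypes["S2", ]), c(0L, 0L))
  expect_equal(gm$markers$snp_id, c("rs1", "rs2"))
})

test_that("missing alleles (0 0) become missing genotypes", {
  dir <- withr::local_tempdir()
  writeLines("1 rs1 0 100", file.path(dir, "m.map"))
  writeLines(c("F S1 0 0 0 -9 A G", "F S2 0 0 0 -9 0 0"),
             file.path(dir, "m.ped"))
  gm <- read_plink_text(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_true(is.na(gm$genotypes["S2", 1]))
  expect_equal(unname(gm$genotypes["S1", 1]), 1L)
})

test_that("malformed PLINK files raise informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "b.map"))
  writeLines(c("F S1 0 0 0 -9 A A A G", "F S2 0 0 0 -9 A A"),
             file.path(dir, "b.ped"))
  expect_error(read_plink_text(file.path(dir, "b.ped"), file.path(dir, "b.map")),
               "line 2")
  expect_error(read_plink_text(file.path(dir, "nope.ped"), file.path(dir, "b.map")),
               "not found")
})

test_that("write/read round-trip is lossless for coding, missingness, order", {
  set.seed(42)
  g <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 20, 50)
  mk <- marker_map(sprintf("s%02d", 1:50), rep(c("1", "2"), each = 25),
                   rep(seq(1e5, 25e5, length.out = 25), 2),
                   allele_a = sample(c("A", "C"), 50, TRUE),
                   allele_b = sample(c("G", "T"), 50, TRUE))
  gm <- genotype_matrix(g, mk, sprintf("ind%02d", 1:20))
  dir <- withr::local_tempdir()
  write_plink_text(gm, file.path(dir, "rt"))
  back <- read_plink_text(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_identical(unname(back$genotypes), unname(gm$genotypes))
  expect_equal(back$markers$snp_id, gm$markers$snp_id)
  expect_equal(back$markers$allele_a, gm$markers$allele_a)
  expect_equal(back$sample_ids, gm$sample_ids)
})

test_that("empty sample set still writes a valid map", {
  mk <- marker_map(c("a", "b"), "1", c(10L, 20L))
  gm <- genotype_matrix(matrix(integer(0), 0, 2), mk, character(0))
  dir <- withr::local_tempdir()
  write_plink_text(gm, file.path(dir, "empty"))
  expect_equal(length(readLines(file.path(dir, "empty.ped"))), 0)
  expect_equal(length(readLines(file.path(dir, "empty.map"))), 2)
})

test_that("masking keeps panel genotypes and blanks the rest", {
  set.seed(7)
  gm <- toy_gm(matrix(sample(0:2, 5 * 10, TRUE), 5, 10))
  panel <- c("snp02", "snp05", "snp09")
  masked <- mask_to_panel(gm, panel)
  keep <- gm$markers$snp_id %in% panel
  expect_identical(masked$genotypes[, keep], gm$genotypes[, keep])
  expect_equal(sum(colSums(is.na(masked$genotypes)) == 5), 7)
  expect_equal(nrow(masked$markers), 10)
  # identity and empty panels
  expect_identical(mask_to_panel(gm, gm$markers$snp_id)$genotypes, gm$genotypes)
  expect_true(all(is.na(mask_to_panel(gm, character(0))$genotypes)))
  expect_error(mask_to_panel(gm, "nope"), "not in marker map")
})

test_that("sample splitting reproduces the 200/490/163 arithmetic", {
  ids <- sprintf("h%03d", 1:853)
  sp <- split_samples(ids, c(A = 200, B = 0.75, C = 0.25), seed = 5)
  expect_equal(unname(sp$sizes), c(200L, 490L, 163L))
  # partition: disjoint, exhaustive
  expect_setequal(unlist(sp$sets), ids)
  expect_equal(sum(lengths(sp$sets)), 853)
  # determinism and seed sensitivity
  sp2 <- split_samples(ids, c(A = 200, B = 0.75, C = 0.25), seed = 5)
  expect_identical(sp$labels, sp2$labels)
  sp3 <- split_samples(ids, c(A = 200, B = 0.75, C = 0.25), seed = 6)
  expect_false(identical(sp$labels, sp3$labels))
})

test_that("degenerate and invalid split specs are handled", {
  ids <- letters[1:10]
  expect_equal(unname(split_samples(ids, c(all = 1.0), seed = 1)$sizes), 10L)
  expect_error(split_samples(ids, c(A = 0.6, B = 0.3), seed = 1), "sum to 1")
  expect_error(split_samples(ids, c(A = 20), seed = 1), "exceed")
})

test_that("the VCF convenience reader recodes diploid GT fields", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT", "0|0", "./.",
          sep = "\t")), vcf)
  gm <- read_vcf_genotypes(vcf)
  expect_equal(unname(gm$genotypes["S1", ]), c(1L, 0L))
  expect_equal(unname(gm$genotypes["S2", c("rs1")]), 2L)
  expect_true(is.na(gm$genotypes["S2", "rs2"]))
  expect_equal(gm$markers$allele_a, c("A", "C"))
})
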