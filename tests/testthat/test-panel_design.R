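test_that("per-chromosome allocation follows largest-remainder proportionality", {
  expect_equal(unname(allocate_snps_per_chromosome(100, c(a = 3, b = 1))),
               c(75L, 25L))
  expect_equal(unname(allocate_snps_per_chromosome(10, c(1, 1, 1))),
               c(4L, 3L, 3L))
  expect_equal(unname(allocate_snps_per_chromosome(17, c(one = 5))), 17L)
  expect_error(allocate_snps_per_chromosome(3, c(1, 1)), "allocation error")
  # floor of 2 per chromosome
  alloc <- allocate_snps_per_chromosome(8, c(100, 1, 1, 1))
  expect_true(all(alloc >= 2))
  expect_equal(sum(alloc), 8)
})

test_that("Ne-scaled density reproduces the printed panel densities", {
  expect_equal(round(panel_density_ne_per_morgan(1000, 27.72, 150), 2), 0.24)
  expect_equal(round(panel_density_ne_per_morgan(6000, 27.72, 150), 2), 1.44)
  expect_equal(panel_density_ne_per_morgan(0, 27.72, 150), 0)
})

test_that("ideal spacing divides the chromosome into n-1 segments", {
  expect_equal(ideal_spacing(100, 3), 50)
  expect_equal(ideal_spacing(100, 101), 1)
  expect_equal(ideal_spacing(185e6, 30), 185e6 / 29)
  expect_error(ideal_spacing(100, 1), "fewer than 2")
})

# independent naive implementation of boundary-nearest selection
bpeq_oracle <- function(pos, n_chr) {
  b <- pos[1] + (pos[length(pos)] - pos[1]) * (0:(n_chr - 1)) / (n_chr - 1)
  used <- integer(0)
  for (x in b) {
    ord <- order(abs(pos - x), pos)
    used <- c(used, setdiff(ord, used)[1])
  }
  sort(used)
}

test_that("equidistant selection matches hand cases and the naive oracle", {
  mk <- marker_map(c("a", "b", "c", "d"), "1", c(1, 48, 52, 99))
  expect_equal(select_bpeq(mk, 3), c("a", "b", "d"))  # tie at 50 -> lower bp
  expect_equal(select_bpeq(mk, 4), mk$snp_id)
  grid <- marker_map(sprintf("g%03d", 1:101), "1", seq(1e6, 101e6, 1e6))
  expect_equal(select_bpeq(grid, 11), sprintf("g%03d", seq(1, 101, 10)))
  set.seed(33)
  for (rep in 1:25) {
    m <- sample(4:25, 1)
    pos <- sort(sample.int(1e6, m))
    mk <- marker_map(sprintf("s%02d", 1:m), "1", pos)
    n <- sample(2:m, 1)
    expect_equal(select_bpeq(mk, n), mk$snp_id[bpeq_oracle(pos, n)])
  }
})

test_that("panel cost combines MAF and normalised spacing penalties", {
  expect_equal(panel_cost(c(0.5, 0.5, 0.5), c(0, 10, 20), d = 10), 0)
  expect_equal(panel_cost(c(0.25, 0.25), c(0, 10), d = 10), 0.125)
  c1 <- panel_cost(c(0.3, 0.2, 0.4), c(0, 7, 20), d = 10)
  c2 <- panel_cost(c(0.3, 0.2, 0.4), c(0, 14, 40), d = 20)
  expect_equal(c1, c2)  # scale invariance of the normalised spacing term
  expect_error(panel_cost(c(0.5, 0.5), c(0, 1), d = 0), "positive")
})

test_that("LDU ties are broken by 1e-6 increments preserving bp order", {
  expect_equal(ldu_tie_adjust(c(0, 1, 1, 1, 2)),
               c(0, 1, 1.000001, 1.000002, 2))
  x <- c(0, 0.5, 1.7, 3)
  expect_identical(ldu_tie_adjust(x), x)
  expect_equal(ldu_tie_adjust(rep(2, 4)), 2 + (0:3) * 1e-6)
  expect_error(ldu_tie_adjust(c(1, 0)), "non-decreasing")
})

test_that("GA selection returns all SNPs when the solution is forced", {
  mk <- marker_map(sprintf("s%d", 1:5), "1", c(1, 10, 20, 30, 40) * 1e5)
  sel <- select_optimized(mk, rep(0.3, 5), "bp", 5, seed = 1)
  expect_equal(as.character(sel), mk$snp_id)
})

test_that("at an LDU spacing tie the higher-MAF SNP wins", {
  mk <- marker_map(sprintf("s%d", 1:4), "1", c(1, 2, 3, 4) * 1e5,
                   ldu_position = c(0, 1, 1, 2))
  sel <- select_optimized(mk, c(0.5, 0.1, 0.5, 0.4), "ldu", 3, seed = 2)
  expect_true("s3" %in% sel)
  expect_false("s2" %in% sel)
})

# steepest-descent local search over single-SNP swaps, as an independent
# optimisation oracle
local_search_cost <- function(coords, mafs, n_chr, lambda = 1) {
  m <- length(coords)
  d <- ideal_spacing(coords[m] - coords[1], n_chr)
  cost_of <- function(int_idx) {
    idx <- c(1L, sort(int_idx), m)
    panel_cost(mafs[idx], coords[idx], d, lambda)
  }
  targets <- coords[1] + (coords[m] - coords[1]) * (1:(n_chr - 2)) / (n_chr - 1)
  cur <- unique(vapply(targets, function(x) which.min(abs(coords - x)), 0L))
  while (length(cur) < n_chr - 2) {
    cur <- unique(c(cur, sample(setdiff(2:(m - 1), cur), 1)))
  }
  best <- cost_of(cur)
  repeat {
    improved <- FALSE
    for (slot in seq_along(cur)) {
      for (cand in setdiff(2:(m - 1), cur)) {
        trial <- cur
        trial[slot] <- cand
        cc <- cost_of(trial)
        if (cc < best - 1e-12) {
          cur <- trial
          best <- cc
          improved <- TRUE
        }
      }
    }
    if (!improved) return(best)
  }
}

test_that("GA matches a local-search oracle and beats equidistant on MAF", {
  set.seed(55)
  m <- 200
  pos <- sort(sample.int(50e6, m))
  mafs <- runif(m, 0.02, 0.5)
  mk <- marker_map(sprintf("s%03d", 1:m), "1", pos)
  sel <- select_optimized(mk, mafs, "bp", 20, seed = 3)
  ls_cost <- local_search_cost(as.numeric(pos), mafs, 20)
  expect_lte(attr(sel, "cost"), attr(sel, "cost_bpeq"))
  expect_lte(attr(sel, "cost"), ls_cost * 1.01)
  eq <- select_bpeq(mk, 20)
  expect_gt(mean(mafs[match(sel, mk$snp_id)]),
            mean(mafs[match(eq, mk$snp_id)]))
})

test_that("GA cost never exceeds the equidistant cost across seeds", {
  set.seed(77)
  pos <- sort(sample.int(10e6, 60))
  mafs <- runif(60, 0.05, 0.5)
  mk <- marker_map(sprintf("s%02d", 1:60), "1", pos)
  for (s in 1:5) {
    sel <- select_optimized(mk, mafs, "bp", 10, seed = s,
                            ga_params = list(generations = 80))
    expect_lte(attr(sel, "cost"), attr(sel, "cost_bpeq"))
  }
})

test_that("designed panels are sorted subsets of the map with forced ends", {
  parts <- pop_small_parts()
  mk <- parts$pop$markers
  for (method in c("bpeq", "bpmaf")) {
    pan <- design_panel(mk, parts$mafs, method, 20, seed = 9)
    ids <- panel_snp_ids(pan)
    expect_true(all(ids %in% mk$snp_id))
    idx <- match(ids, mk$snp_id)
    expect_false(is.unsorted(idx))
    expect_equal(length(ids), 20)
    if (method != "bpeq") {
      expect_true(mk$snp_id[1] %in% ids && mk$snp_id[nrow(mk)] %in% ids)
    }
  }
})
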