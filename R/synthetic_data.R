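#' Simulation configuration for a Thoroughbred-like population
#'
#' Defaults emulate the demography the panel-design analyses assume: a breed
#' founded from a small pool (about 28 effective founders) roughly 30
#' generations ago, maintained at an effective size of about 150, genotyped
#' on a chip ascertained for common variants (MAF >= 0.05).
#'
#' @param ne effective (per-generation) population size (diploids).
#' @param founder_pool number of diploid founders.
#' @param generations_since_founding forward generations from founding to
#'   the sampled generation.
#' @param burn_in_generations pre-founding generations at size `ne` that
#'   bring the source population to drift-recombination equilibrium before
#'   the founders are drawn (default `2 * ne`), so that founder haplotypes
#'   carry realistic ancestral LD rather than independent sites.
#' @param chrom_morgans numeric vector of chromosome genetic lengths in
#'   Morgan (1 Morgan maps to 100 Mb of physical sequence).
#' @param snp_density_per_morgan target ascertained SNP density.
#' @param maf_min_ascertained chip ascertainment MAF threshold (in the
#'   sampled population).
#' @param recomb_profile `NULL` for uniform recombination, or a data.frame
#'   with columns `start_frac`, `end_frac`, `rel_rate` (relative rates over
#'   physical fractions of each chromosome; renormalised so the chromosome
#'   keeps its genetic length). Use [centromere_profile()] for a high-LD
#'   centromeric region.
#' @param split_generations generations before the present at which a
#'   population split occurs (for [simulate_split_populations()]).
#' @param migration_rate per-parent migration probability after the split.
#' @param n_samples individuals sampled from the final generation.
#' @param n_samples2 sample size for the second population (split
#'   simulations); defaults to `n_samples`.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ne = 150, founder_pool = 28,
                       generations_since_founding = 30,
                       burn_in_generations = 2 * ne,
                       chrom_morgans = 1, snp_density_per_morgan = 1300,
                       maf_min_ascertained = 0.05, recomb_profile = NULL,
                       split_generations = 0, migration_rate = 0,
                       n_samples = 853, n_samples2 = NULL, seed = 1) {
  stopifnot(ne >= 2, founder_pool >= 2, generations_since_founding >= 1,
            all(chrom_morgans >= 0), snp_density_per_morgan > 0,
            maf_min_ascertained >= 0, maf_min_ascertained < 0.5,
            split_generations >= 0, migration_rate >= 0, migration_rate <= 1,
            n_samples >= 1)
  if (split_generations > generations_since_founding) {
    stop("split_generations cannot exceed generations_since_founding")
  }
  stopifnot(burn_in_generations >= 0)
  structure(list(ne = as.integer(ne), founder_pool = as.integer(founder_pool),
                 generations_since_founding = as.integer(generations_since_founding),
                 burn_in_generations = as.integer(burn_in_generations),
                 chrom_morgans = chrom_morgans,
                 snp_density_per_morgan = snp_density_per_morgan,
                 maf_min_ascertained = maf_min_ascertained,
                 recomb_profile = recomb_profile,
                 split_generations = as.integer(split_generations),
                 migration_rate = migration_rate,
                 n_samples = as.integer(n_samples),
                 n_samples2 = as.integer(n_samples2 %||% n_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Recombination profile with a suppressed central region
#'
#' A simple stand-in for a centromeric high-LD region: relative rate
#' `rate_rel` over the central `width_frac` of the chromosome, 1 elsewhere
#' (renormalised internally).
#'
#' @param width_frac physical fraction covered by the suppressed region.
#' @param rate_rel relative recombination rate inside it.
#' @param center_frac centre of the region as a physical fraction.
#' @return A recomb_profile data.frame for [sim_config()].
#' @export
centromere_profile <- function(width_frac = 0.2, rate_rel = 0.1,
                               center_frac = 0.5) {
  a <- center_frac - width_frac / 2
  b <- center_frac + width_frac / 2
  data.frame(start_frac = c(0, a, b), end_frac = c(a, b, 1),
             rel_rate = c(1, rate_rel, 1))
}

# physical fraction -> genetic position (Morgan) under a piecewise profile
profile_morgan_map <- function(frac, profile, total_morgan) {
  if (is.null(profile)) return(frac * total_morgan)
  w <- profile$rel_rate * (profile$end_frac - profile$start_frac)
  scale <- total_morgan / sum(w)
  cum <- c(0, cumsum(w)) * scale
  seg <- findInterval(frac, profile$start_frac, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1), nrow(profile))
  cum[seg] + (frac - profile$start_frac[seg]) * profile$rel_rate[seg] * scale
}

# one gamete from a diploid parent (2-row haplotype matrix): Poisson
# crossovers in Morgan coordinates, executed in compiled code
make_gamete <- function(h1, h2, chrom_sites) {
  out <- integer(length(h1))
  parents <- rbind(h1, h2)
  storage.mode(parents) <- "integer"
  for (cs in chrom_sites) {
    rel <- cs$morgan - cs$morgan[1]
    out[cs$idx] <- .wf_gametes_cpp(parents[, cs$idx, drop = FALSE], 0L,
                                   rel, cs$L)[1, ]
  }
  out
}

# advance one Wright-Fisher generation: parents (2P x S haplotype matrix,
# rows 2i-1, 2i belong to parent i) -> n_off offspring haplotypes; with a
# migrant pool, each gamete's parent comes from it with prob migration_rate
next_generation <- function(parents, n_off, chrom_sites,
                            migrants = NULL, migration_rate = 0) {
  np <- nrow(parents) / 2
  ng <- 2L * n_off
  if (!is.null(migrants) && migration_rate > 0) {
    nm <- nrow(migrants) / 2
    pool <- rbind(parents, migrants)
    from_mig <- runif(ng) < migration_rate
    pidx <- integer(ng)
    pidx[!from_mig] <- sample.int(np, sum(!from_mig), replace = TRUE)
    pidx[from_mig] <- np + sample.int(nm, sum(from_mig), replace = TRUE)
  } else {
    pool <- parents
    pidx <- sample.int(np, ng, replace = TRUE)
  }
  storage.mode(pool) <- "integer"
  off <- matrix(0L, ng, ncol(parents))
  for (cs in chrom_sites) {
    rel <- cs$morgan - cs$morgan[1]
    off[, cs$idx] <- .wf_gametes_cpp(pool[, cs$idx, drop = FALSE],
                                     pidx - 1L, rel, cs$L)
  }
  off
}

# shared simulation core: candidate-site bookkeeping plus the initial
# (pre-burn-in) haplotype pool; candidate sites are over-generated because
# drift during burn-in and breed history fixes a sizeable fraction, then
# ascertained after sampling
sim_core <- function(cfg) {
  mult <- if (cfg$burn_in_generations > 0) 8 else 3
  n_cand_per <- pmax(4L, ceiling(mult * cfg$snp_density_per_morgan *
                                   pmax(cfg$chrom_morgans, 0.05)))
  chrom_sites <- list()
  bp_all <- integer(0); chr_all <- character(0); morgan_all <- numeric(0)
  offset <- 0L
  for (c_i in seq_along(cfg$chrom_morgans)) {
    Lm <- cfg$chrom_morgans[c_i]
    L_bp <- max(1e6, Lm * 1e8)  # 1 cM per Mb; floor for zero-recomb chromosomes
    nc <- n_cand_per[c_i]
    frac <- sort(runif(nc))
    bp <- as.integer(round(frac * (L_bp - 1)) + 1)
    # enforce strictly increasing bp
    while (any(duplicated(bp))) bp[duplicated(bp)] <- bp[duplicated(bp)] + 1L
    bp <- sort(bp)
    frac <- (bp - 1) / (L_bp - 1)
    morgan <- profile_morgan_map(frac, cfg$recomb_profile, Lm)
    chrom_sites[[c_i]] <- list(idx = offset + seq_len(nc), morgan = morgan,
                               L = Lm)
    bp_all <- c(bp_all, bp)
    chr_all <- c(chr_all, rep(as.character(c_i), nc))
    morgan_all <- c(morgan_all, morgan)
    offset <- offset + nc
  }
  S <- offset
  # initial haplotype pool: chip-flat common spectrum, sites independent;
  # burn-in then builds equilibrium LD before the founders are drawn
  p0 <- runif(S, 0.05, 0.95)
  init <- matrix(rbinom(2 * cfg$ne * S, 1, rep(p0, each = 2 * cfg$ne)),
                 nrow = 2 * cfg$ne, ncol = S)
  list(init = init, chrom_sites = chrom_sites, bp = bp_all,
       chr = chr_all, morgan = morgan_all)
}

# ancestral equilibration + founder bottleneck + breed history, returning
# the final parental haplotype pool
sim_breed_parents <- function(cfg, core, generations) {
  chrom_start <- vapply(core$chrom_sites, function(cs) cs$idx[1] - 1L, 0L)
  morgan_rel <- unlist(lapply(core$chrom_sites,
                              function(cs) cs$morgan - cs$morgan[1]))
  L <- vapply(core$chrom_sites, function(cs) cs$L, 0)
  evolve <- function(pop, gens) {
    if (gens == 0) return(pop)
    storage.mode(pop) <- "integer"
    .wf_evolve_cpp(pop, as.integer(gens), cfg$ne, as.integer(chrom_start),
                   morgan_rel, L)
  }
  pop <- evolve(core$init, cfg$burn_in_generations)
  fid <- sample.int(cfg$ne, min(cfg$founder_pool, cfg$ne))
  pop <- pop[as.vector(rbind(2L * fid - 1L, 2L * fid)), , drop = FALSE]
  evolve(pop, generations)
}

# ascertain candidate sites on a sampled haplotype matrix and thin to the
# target density, keeping coverage even along each chromosome
ascertain_sites <- function(hap, core, cfg) {
  maf <- pmin(colMeans(hap), 1 - colMeans(hap))
  keep_all <- integer(0)
  for (c_i in seq_along(cfg$chrom_morgans)) {
    idx <- core$chrom_sites[[c_i]]$idx
    surv <- idx[maf[idx] >= cfg$maf_min_ascertained]
    target <- max(2L, round(cfg$snp_density_per_morgan *
                              max(cfg$chrom_morgans[c_i], 0.05)))
    if (length(surv) < target) {
      stop("simulation error: only ", length(surv), " segregating sites meet ",
           "the ascertainment MAF on chromosome ", c_i, " (need ", target,
           "); increase founder_pool or lower snp_density_per_morgan")
    }
    pick <- unique(round(seq(1, length(surv), length.out = target)))
    keep_all <- c(keep_all, surv[pick])
  }
  sort(keep_all)
}

hap_to_gm <- function(hap, core, keep, ids) {
  n <- nrow(hap) / 2
  g <- hap[seq(1, 2 * n, 2), keep, drop = FALSE] +
    hap[seq(2, 2 * n, 2), keep, drop = FALSE]
  mk <- marker_map(
    snp_id = sprintf("c%s_s%06d", core$chr[keep], keep),
    chromosome = core$chr[keep],
    bp_position = core$bp[keep],
    allele_a = "A", allele_b = "B",
    morgan_position = core$morgan[keep]
  )
  genotype_matrix(g, mk, ids, phased = hap[, keep, drop = FALSE])
}

#' Simulate a chip-genotyped population
#'
#' Forward-in-time Wright-Fisher simulation of diploids: founder haplotypes
#' carry independent common variants (a chip-flat frequency spectrum), the
#' population then evolves for `generations_since_founding` generations at
#' size `ne` with Poisson crossovers placed by the recombination profile,
#' and `n_samples` individuals are bred from the final parental generation.
#' Candidate sites are over-generated and then ascertained to the chip MAF
#' threshold and thinned to the target density. No new mutations arise
#' after founding (negligible over ~30 generations).
#'
#' @param cfg a [sim_config()].
#' @return A phased [genotype_matrix()] whose marker map carries truth
#'   `morgan_position` coordinates.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    core <- sim_core(cfg)
    pop <- sim_breed_parents(cfg, core, cfg$generations_since_founding)
    hap <- next_generation(pop, cfg$n_samples, core$chrom_sites)
    keep <- ascertain_sites(hap, core, cfg)
    hap_to_gm(hap, core, keep, sprintf("I%04d", seq_len(cfg$n_samples)))
  })
}

#' Simulate two recently diverged populations
#'
#' A single ancestral population evolves for
#' `generations_since_founding - split_generations` generations, then splits
#' into two populations of size `ne` that exchange migrants at
#' `migration_rate` per parent per generation for the remaining
#' `split_generations`. Sites are ascertained on the population-1 sample
#' (the panel-design population) and the same sites are reported for both.
#'
#' @param cfg a [sim_config()] with `split_generations` and
#'   `migration_rate` set.
#' @return A list with phased genotype matrices `pop1` and `pop2` (shared
#'   marker map) and `freq_correlation`, the per-SNP allele-frequency
#'   correlation between the two samples.
#' @export
simulate_split_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    core <- sim_core(cfg)
    shared <- cfg$generations_since_founding - cfg$split_generations
    pop <- sim_breed_parents(cfg, core, shared)
    popA <- pop
    popB <- pop
    if (cfg$split_generations > 0) {
      for (g in seq_len(cfg$split_generations)) {
        newA <- next_generation(popA, cfg$ne, core$chrom_sites,
                                migrants = popB,
                                migration_rate = cfg$migration_rate)
        newB <- next_generation(popB, cfg$ne, core$chrom_sites,
                                migrants = popA,
                                migration_rate = cfg$migration_rate)
        popA <- newA
        popB <- newB
      }
    }
    hapA <- next_generation(popA, cfg$n_samples, core$chrom_sites)
    hapB <- next_generation(popB, cfg$n_samples2, core$chrom_sites)
    keep <- ascertain_sites(hapA, core, cfg)
    gm1 <- hap_to_gm(hapA, core, keep, sprintf("P1_%04d", seq_len(cfg$n_samples)))
    gm2 <- hap_to_gm(hapB, core, keep, sprintf("P2_%04d", seq_len(cfg$n_samples2)))
    f1 <- allele_freqs(gm1)
    f2 <- allele_freqs(gm2)
    list(pop1 = gm1, pop2 = gm2,
         freq_correlation = cor(f1, f2))
  })
}

#' Append half-sib families to a simulated population
#'
#' Emulates a sampling scheme rich in paternal half-sibs: for each family a
#' sire is drawn from the existing samples and `size` offspring are bred
#' from it with distinct random dams. Requires truth phase and Morgan
#' coordinates (i.e. a simulated population).
#'
#' @param pop a phased [genotype_matrix()] from [simulate_population()].
#' @param families list with `n` (number of families) and `size` (offspring
#'   per family).
#' @param seed integer seed.
#' @return The population with offspring appended; the truth pedigree
#'   (offspring, sire, dam) is attached as attribute `"pedigree"`.
#' @export
add_half_sib_structure <- function(pop, families, seed = 1) {
  if (is.null(families$n) || families$n == 0) return(pop)
  if (is.null(families$size) || families$size < 1) {
    stop("family size must be at least 1")
  }
  if (is.null(pop$phased)) stop("half-sib construction needs truth phase")
  if (is.null(pop$markers$morgan_position)) {
    stop("half-sib construction needs Morgan coordinates")
  }
  n <- length(pop$sample_ids)
  if (n < families$n + 1) stop("not enough parents available")
  mk <- pop$markers
  chrom_sites <- lapply(unique(mk$chromosome), function(ch) {
    idx <- which(mk$chromosome == ch)
    list(idx = idx, morgan = mk$morgan_position[idx],
         L = max(mk$morgan_position[idx]) - min(mk$morgan_position[idx]))
  })
  with_seed(seed, {
    sires <- sample.int(n, families$n)
    new_h <- list(); ped <- list()
    for (f in seq_len(families$n)) {
      s <- sires[f]
      for (k in seq_len(families$size)) {
        d <- sample(setdiff(seq_len(n), s), 1)
        g1 <- make_gamete(pop$phased[2 * s - 1, ], pop$phased[2 * s, ],
                          chrom_sites)
        g2 <- make_gamete(pop$phased[2 * d - 1, ], pop$phased[2 * d, ],
                          chrom_sites)
        new_h[[length(new_h) + 1]] <- rbind(g1, g2)
        ped[[length(ped) + 1]] <- data.frame(
          offspring = sprintf("HS%02d_%03d", f, k),
          sire = pop$sample_ids[s], dam = pop$sample_ids[d],
          stringsAsFactors = FALSE)
      }
    }
    ped <- do.call(rbind, ped)
    hap_new <- do.call(rbind, new_h)
    hap <- rbind(pop$phased, hap_new)
    g_new <- hap_new[seq(1, nrow(hap_new), 2), , drop = FALSE] +
      hap_new[seq(2, nrow(hap_new), 2), , drop = FALSE]
    out <- genotype_matrix(rbind(pop$genotypes, g_new), mk,
                           c(pop$sample_ids, ped$offspring), phased = hap)
    attr(out, "pedigree") <- ped
    out
  })
}

#' Write a simulated population with its truth bundle
#'
#' PLINK text plus a phased-haplotype TSV, a Morgan-position map and the
#' configuration echoed as JSON.
#'
#' @param pop a phased [genotype_matrix()].
#' @param prefix output path prefix.
#' @param cfg optional [sim_config()] to echo.
#' @return Invisibly, the paths written.
#' @export
write_truth_bundle <- function(pop, prefix, cfg = NULL) {
  paths <- write_plink_text(pop, prefix)
  hp <- paste0(prefix, ".haplotypes.tsv")
  hap <- as.data.frame(pop$phased)
  names(hap) <- pop$markers$snp_id
  hap <- cbind(sample_id = rep(pop$sample_ids, each = 2),
               haplotype = rep(1:2, length(pop$sample_ids)), hap)
  write.table(hap, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- paste0(prefix, ".morgan.tsv")
  write.table(data.frame(snp_id = pop$markers$snp_id,
                         chromosome = pop$markers$chromosome,
                         morgan = pop$markers$morgan_position),
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(paths, haplotypes = hp, morgan = mp)
  if (!is.null(cfg)) {
    cp <- paste0(prefix, ".config.json")
    jsonlite::write_json(unclass(cfg), cp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    out <- c(out, config = cp)
  }
  invisible(out)
}
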