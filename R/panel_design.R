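#' Allocate panel SNP counts across chromosomes
#'
#' Counts are proportional to physical chromosome length
#' (`round(total * len_chr / len_genome)`), reconciled to sum exactly to
#' `total` by the largest-remainder rule with ties broken in chromosome
#' order, and every chromosome receives at least 2 SNPs (so both chromosome
#' ends can be covered).
#'
#' @param total total panel size across the genome.
#' @param len_bp numeric vector of chromosome lengths in bp (named by
#'   chromosome).
#' @return Integer vector of per-chromosome counts summing to `total`.
#' @export
allocate_snps_per_chromosome <- function(total, len_bp) {
  k <- length(len_bp)
  stopifnot(k >= 1, all(len_bp > 0))
  if (total < 2 * k) {
    stop("allocation error: total ", total, " cannot give each of ", k,
         " chromosomes at least 2 SNPs")
  }
  exact <- total * len_bp / sum(len_bp)
  counts <- floor(exact)
  rem <- exact - counts
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(-rem, seq_len(k))  # largest remainder, tie: chromosome order
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  # enforce the 2-SNP floor, taking from the most generously served donor
  # (a chromosome with > 2 always exists while any is below 2, since the
  # counts sum to total >= 2k)
  while (any(counts < 2)) {
    i <- which(counts < 2)[1]
    donors <- which(counts > 2)
    j <- donors[which.max(counts[donors] - exact[donors])]
    counts[j] <- counts[j] - 1
    counts[i] <- counts[i] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- names(len_bp)
  counts
}

#' Panel density in Ne-scaled SNPs per Morgan
#'
#' Expresses a panel size as `panel_size / (genome_morgans * ne)`, the
#' density normalisation that makes low-density panels comparable across
#' species with different effective population sizes.
#'
#' @param panel_size number of panel SNPs.
#' @param genome_morgans total genome genetic length in Morgan.
#' @param ne effective population size.
#' @return Density in Ne SNPs per Morgan.
#' @export
panel_density_ne_per_morgan <- function(panel_size, genome_morgans, ne) {
  stopifnot(genome_morgans > 0, ne > 0, panel_size >= 0)
  panel_size / (genome_morgans * ne)
}

#' Ideal spacing between panel SNPs
#'
#' @param len_chr chromosome length in the active coordinate system (bp or
#'   LDU).
#' @param n_chr number of panel SNPs on the chromosome (>= 2).
#' @return `len_chr / (n_chr - 1)`.
#' @export
ideal_spacing <- function(len_chr, n_chr) {
  if (n_chr < 2) stop("ideal spacing undefined for fewer than 2 SNPs")
  len_chr / (n_chr - 1)
}

#' Equidistant panel selection (bpEQ)
#'
#' Divides the chromosome span (anchored at the first and last SNP
#' positions) into `n_chr - 1` equal segments and picks the SNP closest to
#' each segment boundary, irrespective of MAF. Distance ties are broken to
#' the lower bp position; a boundary whose nearest SNP is already taken gets
#' the next-nearest unused SNP.
#'
#' @param markers a [marker_map()] for a single chromosome.
#' @param n_chr number of SNPs to select (>= 2).
#' @return Character vector of selected SNP ids, sorted by position.
#' @export
select_bpeq <- function(markers, n_chr) {
  if (n_chr < 2) stop("n_chr must be >= 2")
  if (length(unique(markers$chromosome)) > 1) {
    stop("select_bpeq operates on a single chromosome")
  }
  m <- nrow(markers)
  if (m == 0) stop("empty marker map")
  if (n_chr >= m) {
    if (n_chr > m) warning("requested ", n_chr, " SNPs but only ", m,
                           " available; returning all")
    return(markers$snp_id)
  }
  pos <- as.numeric(markers$bp_position)
  boundaries <- pos[1] + (pos[m] - pos[1]) * (0:(n_chr - 1)) / (n_chr - 1)
  chosen <- integer(0)
  for (b in boundaries) {
    dist <- abs(pos - b)
    dist[chosen] <- Inf
    j <- which(dist == min(dist))[1]  # tie -> lower bp (first index)
    chosen <- c(chosen, j)
  }
  markers$snp_id[sort(chosen)]
}

#' Panel objective: MAF informativeness plus spacing regularity
#'
#' The cost of an ordered panel is
#' `sum_i (0.5 - MAF_i)^2 + lambda * sum_i ((S_{i+1} - S_i)/d - 1)^2`,
#' driving MAF towards 0.5 while keeping consecutive spacings near the ideal
#' distance `d`. The spacing deviation is normalised by `d` before squaring
#' so the two terms are commensurate regardless of the coordinate scale (a
#' raw squared bp deviation would dwarf the MAF term by many orders of
#' magnitude).
#'
#' @param mafs MAFs of the selected SNPs, in position order.
#' @param coords coordinates (bp or LDU) of the selected SNPs, sorted
#'   increasing.
#' @param d ideal spacing in the same coordinate system (> 0).
#' @param lambda_spacing weight on the spacing term (default 1).
#' @return The scalar cost.
#' @export
panel_cost <- function(mafs, coords, d, lambda_spacing = 1) {
  if (d <= 0) stop("ideal spacing d must be positive")
  if (length(mafs) != length(coords) || length(mafs) < 2) {
    stop("need >= 2 selected SNPs with matching MAF and coordinate vectors")
  }
  if (is.unsorted(coords)) stop("coords must be sorted increasing")
  gaps <- diff(coords)
  sum((0.5 - mafs)^2) + lambda_spacing * sum((gaps / d - 1)^2)
}

#' Break LDU coordinate ties
#'
#' SNPs mapped to identical LDU positions get a small strictly increasing
#' offset (k * 1e-6 for the k-th member of an equal run) so SNP order stays
#' consistent with the physical map.
#'
#' @param ldu_positions non-decreasing numeric vector.
#' @param increment offset step (default 1e-6).
#' @return Strictly increasing vector.
#' @export
ldu_tie_adjust <- function(ldu_positions, increment = 1e-6) {
  if (is.unsorted(ldu_positions)) stop("ldu_positions must be non-decreasing")
  x <- ldu_positions
  r <- rle(x)
  offs <- unlist(lapply(r$lengths, function(l) seq_len(l) - 1L), use.names = FALSE)
  x <- x + offs * increment
  # a natural gap smaller than the accumulated offsets could still produce a
  # decrease; push such positions up so the map stays strictly increasing
  for (i in seq_along(x)[-1]) {
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + increment
  }
  x
}

#' MAF-and-spacing optimised panel selection by a genetic algorithm
#'
#' Selects `n_chr` SNPs on one chromosome minimising [panel_cost()]. The
#' outermost SNPs are always included (telomere rule: chromosome ends
#' recombine more, so coverage there protects imputation). Interior SNPs are
#' encoded one gene per panel slot (a marker index); the initial population
#' mixes the equidistant solution with jittered and random variants;
#' selection is by tournament, recombination by one-point crossover with a
#' sort/deduplicate/refill repair, and mutation moves a gene to a nearby
#' marker. The equidistant solution is always a member and elitism keeps the
#' best individual, so the returned cost never exceeds the equidistant
#' panel's cost under the same objective.
#'
#' @param markers a [marker_map()] for a single chromosome.
#' @param mafs per-SNP MAF aligned with `markers` rows.
#' @param coordinate_system `"bp"` or `"ldu"`; `"ldu"` requires an
#'   `ldu_position` column (tie-adjusted via [ldu_tie_adjust()]).
#' @param n_chr number of SNPs to select (>= 2).
#' @param ga_params list overriding defaults: `pop_size` (60),
#'   `generations` (300), `tournament` (3), `p_crossover` (0.9),
#'   `p_mutation` (0.1 per gene), `stagnation` (50), `lambda_spacing` (1).
#' @param seed integer seed for the GA's randomness.
#' @return Character vector of selected SNP ids sorted by position, with
#'   attributes `cost`, `cost_bpeq` and `d` (ideal spacing used).
#' @export
select_optimized <- function(markers, mafs, coordinate_system = c("bp", "ldu"),
                             n_chr, ga_params = list(), seed = 1) {
  coordinate_system <- match.arg(coordinate_system)
  if (n_chr < 2) stop("n_chr must be >= 2")
  if (length(unique(markers$chromosome)) > 1) {
    stop("select_optimized operates on a single chromosome")
  }
  m <- nrow(markers)
  if (length(mafs) != m) stop("mafs must align with markers")
  if (n_chr >= m) {
    if (n_chr > m) warning("requested ", n_chr, " SNPs but only ", m,
                           " available; returning all")
    sel <- markers$snp_id
    coords <- if (coordinate_system == "bp") as.numeric(markers$bp_position)
              else ldu_tie_adjust(markers$ldu_position)
    d <- if (m >= 2) ideal_spacing(coords[m] - coords[1], m) else NA_real_
    cost <- if (m >= 2) panel_cost(mafs, coords, d) else NA_real_
    return(structure(sel, cost = cost, cost_bpeq = cost, d = d))
  }
  coords <- if (coordinate_system == "bp") {
    as.numeric(markers$bp_position)
  } else {
    if (is.null(markers$ldu_position)) stop("ldu coordinates required but absent")
    ldu_tie_adjust(markers$ldu_position)
  }
  d <- ideal_spacing(coords[m] - coords[1], n_chr)

  p <- modifyList(list(pop_size = 60, generations = 300, tournament = 3,
                       p_crossover = 0.9, p_mutation = 0.1, stagnation = 50,
                       lambda_spacing = 1), ga_params)
  n_int <- n_chr - 2L              # interior slot count (ends forced)
  interior <- 2:(m - 1)            # candidate marker indices for interior slots

  cost_of <- function(int_idx) {
    idx <- c(1L, int_idx, m)
    panel_cost(mafs[idx], coords[idx], d, p$lambda_spacing)
  }
  # equidistant-in-coordinate seed solution (ends forced), also the benchmark
  eq_interior <- function() {
    if (n_int == 0) return(integer(0))
    targets <- coords[1] + (coords[m] - coords[1]) * (1:n_int) / (n_chr - 1)
    taken <- c(1L, m)
    out <- integer(n_int)
    for (s in seq_len(n_int)) {
      dist <- abs(coords - targets[s])
      dist[taken] <- Inf
      j <- which.min(dist)
      out[s] <- j
      taken <- c(taken, j)
    }
    sort(out)
  }
  repair <- function(int_idx) {
    int_idx <- sort(unique(pmin(pmax(int_idx, 2L), m - 1L)))
    while (length(int_idx) < n_int) {
      # refill from unused interior markers nearest the largest gap midpoints
      free <- setdiff(interior, int_idx)
      full <- c(1L, int_idx, m)
      gaps <- diff(coords[full])
      gi <- which.max(gaps)
      mid <- (coords[full[gi]] + coords[full[gi + 1]]) / 2
      int_idx <- sort(c(int_idx, free[which.min(abs(coords[free] - mid))]))
    }
    int_idx
  }

  eqi <- eq_interior()
  cost_bpeq <- cost_of(eqi)
  if (n_int == 0) {
    sel <- markers$snp_id[c(1L, m)]
    return(structure(sel, cost = cost_bpeq, cost_bpeq = cost_bpeq, d = d))
  }

  with_seed(seed, {
    pop <- vector("list", p$pop_size)
    pop[[1]] <- eqi
    for (i in seq_len(p$pop_size)[-1]) {
      if (i <= ceiling(p$pop_size / 2)) {
        jit <- eqi + sample(-3:3, n_int, replace = TRUE)
        pop[[i]] <- repair(jit)
      } else {
        pop[[i]] <- sort(sample(interior, n_int))
      }
    }
    fit <- vapply(pop, cost_of, 0)
    best <- which.min(fit)
    best_sol <- pop[[best]]; best_cost <- fit[best]
    stagnant <- 0L
    for (gen in seq_len(p$generations)) {
      newpop <- vector("list", p$pop_size)
      newpop[[1]] <- best_sol  # elitism
      for (i in 2:p$pop_size) {
        pick <- function() {
          cand <- sample.int(p$pop_size, p$tournament)
          pop[[cand[which.min(fit[cand])]]]
        }
        child <- pick()
        if (runif(1) < p$p_crossover) {
          mate <- pick()
          cut <- sample.int(n_int, 1)
          child <- c(child[seq_len(cut)], mate[-seq_len(cut)])
        }
        mut <- runif(n_int) < p$p_mutation
        if (any(mut)) {
          step <- sample(c(-3:-1, 1:3), sum(mut), replace = TRUE)
          child[mut] <- child[mut] + step
        }
        newpop[[i]] <- repair(child)
      }
      pop <- newpop
      fit <- vapply(pop, cost_of, 0)
      gbest <- which.min(fit)
      if (fit[gbest] < best_cost - 1e-12) {
        best_cost <- fit[gbest]
        best_sol <- pop[[gbest]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= p$stagnation) break
      }
    }
    structure(markers$snp_id[c(1L, best_sol, m)],
              cost = best_cost, cost_bpeq = cost_bpeq, d = d)
  })
}

#' Design a low-density panel across chromosomes
#'
#' Allocates the target panel size across chromosomes by physical length and
#' runs the requested selection method per chromosome: `"bpeq"`
#' (equidistant), `"bpmaf"` (GA-optimised in bp) or `"ldumaf"` (GA-optimised
#' in LD units).
#'
#' @param markers a [marker_map()] (post-QC).
#' @param mafs per-SNP MAF aligned with `markers` rows (design-set MAF).
#' @param method one of `"bpeq"`, `"bpmaf"`, `"ldumaf"`.
#' @param total target genome-wide panel size.
#' @param ldu_maps named list of `ldu_map` objects per chromosome (required
#'   for `"ldumaf"`).
#' @param ga_params,seed passed to [select_optimized()].
#' @return A list of class `ldp_panel`: `method`, `target_total`,
#'   `per_chromosome` (named list of SNP-id vectors sorted by position),
#'   `d_used`, `coordinate_system`, `cost`, `cost_bpeq`, `seed`.
#' @export
design_panel <- function(markers, mafs, method = c("bpeq", "bpmaf", "ldumaf"),
                         total, ldu_maps = NULL, ga_params = list(), seed = 1) {
  method <- match.arg(method)
  chroms <- unique(markers$chromosome)
  len_bp <- vapply(chroms, function(ch) {
    bp <- markers$bp_position[markers$chromosome == ch]
    as.numeric(max(bp) - min(bp))
  }, 0)
  counts <- allocate_snps_per_chromosome(total, len_bp)
  per <- list(); d_used <- numeric(0); cost <- 0; cost_bpeq <- 0
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    rows <- markers$chromosome == ch
    mk <- markers[rows, , drop = FALSE]
    class(mk) <- c("marker_map", "data.frame")
    mf <- mafs[rows]
    n_chr <- counts[ci]
    if (method == "bpeq") {
      sel <- select_bpeq(mk, n_chr)
      d_used[ch] <- ideal_spacing(max(mk$bp_position) - min(mk$bp_position), n_chr)
      idx <- match(sel, mk$snp_id)
      cost <- cost + panel_cost(mf[idx], as.numeric(mk$bp_position[idx]),
                                d_used[ch])
      cost_bpeq <- cost
    } else {
      if (method == "ldumaf") {
        if (is.null(ldu_maps[[ch]])) {
          stop("ldumaf requires an LDU map for chromosome ", ch)
        }
        lm_ <- ldu_maps[[ch]]
        mk$ldu_position <- lm_$ldu_positions[match(mk$snp_id, lm_$snp_ids)]
        if (anyNA(mk$ldu_position)) {
          stop("LDU map for chromosome ", ch, " does not cover all QC'd SNPs")
        }
      }
      sel <- select_optimized(mk, mf,
                              coordinate_system = if (method == "bpmaf") "bp" else "ldu",
                              n_chr = n_chr, ga_params = ga_params,
                              seed = seed + ci)
      d_used[ch] <- attr(sel, "d")
      cost <- cost + attr(sel, "cost")
      cost_bpeq <- cost_bpeq + attr(sel, "cost_bpeq")
    }
    per[[ch]] <- as.character(sel)
  }
  structure(list(method = method, target_total = as.integer(total),
                 per_chromosome = per, d_used = d_used,
                 coordinate_system = if (method == "ldumaf") "ldu" else "bp",
                 cost = cost, cost_bpeq = cost_bpeq, seed = seed),
            class = "ldp_panel")
}

#' SNP ids of a panel
#'
#' @param panel an `ldp_panel` or character vector.
#' @return Character vector of panel SNP ids.
#' @export
panel_snp_ids <- function(panel) {
  if (is.character(panel)) return(panel)
  unlist(panel$per_chromosome, use.names = FALSE)
}

#' @export
print.ldp_panel <- function(x, ...) {
  cat("ldp_panel: method ", x$method, ", ", length(panel_snp_ids(x)),
      " SNPs on ", length(x$per_chromosome), " chromosome(s) (",
      x$coordinate_system, " coordinates)\n", sep = "")
  invisible(x)
}
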