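#' Construct a marker map
#'
#' A marker map is an ordered table of biallelic SNPs. Genotypes elsewhere in
#' the package are allele counts of `allele_b`, so that homozygotes for
#' `allele_a` are coded 0, heterozygotes 1 and homozygotes for `allele_b` 2.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome character (or coercible) chromosome labels.
#' @param bp_position integer 1-based physical positions, strictly increasing
#'   within a chromosome.
#' @param allele_a,allele_b single-character allele labels; `allele_a` is the
#'   allele counted as 0.
#' @param ldu_position optional non-negative LD-unit coordinates,
#'   non-decreasing within a chromosome.
#' @param morgan_position optional genetic-map coordinates in Morgan.
#' @return A `data.frame` of class `marker_map`, sorted by
#'   (chromosome, bp_position).
#' @export
marker_map <- function(snp_id, chromosome, bp_position,
                       allele_a = "A", allele_b = "B",
                       ldu_position = NULL, morgan_position = NULL) {
  m <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    bp_position = as.integer(bp_position),
    allele_a = rep_len(as.character(allele_a), length(snp_id)),
    allele_b = rep_len(as.character(allele_b), length(snp_id)),
    stringsAsFactors = FALSE
  )
  if (!is.null(ldu_position)) m$ldu_position <- as.numeric(ldu_position)
  if (!is.null(morgan_position)) m$morgan_position <- as.numeric(morgan_position)
  m <- m[order(m$chromosome, m$bp_position), , drop = FALSE]
  rownames(m) <- NULL
  validate_marker_map(m)
  class(m) <- c("marker_map", "data.frame")
  m
}

validate_marker_map <- function(m) {
  if (anyDuplicated(m$snp_id)) stop("marker map: snp_id values must be unique")
  for (chr in unique(m$chromosome)) {
    bp <- m$bp_position[m$chromosome == chr]
    if (any(diff(bp) <= 0)) {
      stop("marker map: bp_position must be strictly increasing within chromosome ", chr)
    }
    if (!is.null(m$ldu_position)) {
      ldu <- m$ldu_position[m$chromosome == chr]
      if (any(!is.na(ldu)) && any(diff(ldu) < 0, na.rm = TRUE)) {
        stop("marker map: ldu_position must be non-decreasing within chromosome ", chr)
      }
    }
  }
  invisible(m)
}

#' Construct a genotype matrix object
#'
#' @param genotypes integer matrix (samples x SNPs) with values in 0/1/2 or
#'   `NA` for missing; the count of `allele_b` copies.
#' @param markers a [marker_map()] whose rows match the genotype columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param phased optional phased haplotype matrix (2*samples x SNPs, values
#'   0/1); consecutive row pairs belong to one sample and their per-site sum
#'   must equal the genotype.
#' @return A list of class `genotype_matrix` with elements `genotypes`,
#'   `markers`, `sample_ids` and optionally `phased`.
#' @export
genotype_matrix <- function(genotypes, markers, sample_ids = NULL,
                            phased = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (ncol(genotypes) != nrow(markers)) {
    stop("genotype columns (", ncol(genotypes), ") do not match marker rows (",
         nrow(markers), ")")
  }
  if (nrow(genotypes) != length(sample_ids)) {
    stop("genotype rows do not match sample_ids")
  }
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(sample_ids, markers$snp_id)
  obj <- list(genotypes = genotypes, markers = markers,
              sample_ids = as.character(sample_ids))
  if (!is.null(phased)) {
    phased <- as.matrix(phased)
    storage.mode(phased) <- "integer"
    if (nrow(phased) != 2 * length(sample_ids) || ncol(phased) != nrow(markers)) {
      stop("phased haplotypes must be 2*samples x SNPs")
    }
    gsum <- phased[seq(1, nrow(phased), by = 2), , drop = FALSE] +
      phased[seq(2, nrow(phased), by = 2), , drop = FALSE]
    mism <- !is.na(genotypes) & (gsum != genotypes)
    if (any(mism)) stop("phased haplotype sums disagree with genotypes")
    obj$phased <- phased
  }
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$markers), "SNPs on",
      length(unique(x$markers$chromosome)), "chromosome(s);",
      if (is.null(x$phased)) "unphased" else "phased", "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm a [genotype_matrix()].
#' @param samples character sample ids (or logical/integer index) to keep.
#' @param snps character SNP ids (or logical/integer index) to keep.
#' @return A `genotype_matrix` restricted to the requested rows/columns;
#'   phased haplotypes are carried along.
#' @export
subset_gm <- function(gm, samples = NULL, snps = NULL) {
  ridx <- seq_along(gm$sample_ids)
  if (!is.null(samples)) {
    ridx <- if (is.character(samples)) match(samples, gm$sample_ids) else ridx[samples]
    if (anyNA(ridx)) stop("unknown sample id(s)")
  }
  cidx <- seq_len(nrow(gm$markers))
  if (!is.null(snps)) {
    cidx <- if (is.character(snps)) match(snps, gm$markers$snp_id) else cidx[snps]
    if (anyNA(cidx)) stop("unknown SNP id(s)")
    cidx <- sort(cidx)
  }
  mk <- gm$markers[cidx, , drop = FALSE]
  rownames(mk) <- NULL
  class(mk) <- c("marker_map", "data.frame")
  ph <- NULL
  if (!is.null(gm$phased)) {
    hrows <- as.vector(rbind(2L * ridx - 1L, 2L * ridx))
    ph <- gm$phased[hrows, cidx, drop = FALSE]
  }
  genotype_matrix(gm$genotypes[ridx, cidx, drop = FALSE], mk,
                  gm$sample_ids[ridx], phased = ph)
}

#' Allele-b frequencies of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector: per-SNP frequency of `allele_b` among
#'   non-missing genotypes (`NaN` for all-missing columns).
#' @export
allele_freqs <- function(gm) {
  colMeans(gm$genotypes, na.rm = TRUE) / 2
}

#' Read genotypes from PLINK text files
#'
#' Reads whitespace-delimited `.ped`/`.map` files (missing alleles coded "0").
#' Genotypes are recoded to counts of `allele_b`. Allele orientation: if a
#' companion reference-allele file `<prefix>.ref` (columns snp_id, allele_a,
#' allele_b) exists next to the `.ped`, it fixes the orientation; otherwise
#' `allele_a` is the major allele in the read data (ties broken to the first
#' allele observed in file order). The orientation used is recorded in the
#' returned marker map so coding is stable across datasets.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @param ref_path optional path to a reference-allele file; defaults to
#'   `<prefix>.ref` when that file exists.
#' @return A [genotype_matrix()] (markers sorted by chromosome, bp).
#' @export
read_plink_text <- function(ped_path, map_path, ref_path = NULL) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nfld <- lengths(map_tok)
  if (any(nfld < 4)) {
    stop("malformed .map line ", which(nfld < 4)[1], ": expected 4 fields")
  }
  map <- data.frame(
    chromosome = vapply(map_tok, `[`, "", 1L),
    snp_id = vapply(map_tok, `[`, "", 2L),
    cm = as.numeric(vapply(map_tok, `[`, "", 3L)),
    bp_position = as.integer(vapply(map_tok, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop("dimension error in .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tok))
    }
    ids[i] <- tok[2]
    g <- tok[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * m, by = 2)]
    a2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  if (anyDuplicated(ids)) ids <- paste(vapply(strsplit(trimws(ped_lines), "[ \t]+"), `[`, "", 1L), ids, sep = "_")

  ref <- NULL
  if (is.null(ref_path)) {
    cand <- sub("\\.ped$", ".ref", ped_path)
    if (cand != ped_path && file.exists(cand)) ref_path <- cand
  }
  if (!is.null(ref_path) && file.exists(ref_path)) {
    ref <- read.table(ref_path, header = TRUE, stringsAsFactors = FALSE)
  }

  geno <- matrix(NA_integer_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    if (!is.null(ref)) {
      k <- match(map$snp_id[j], ref$snp_id)
      if (is.na(k)) stop("SNP ", map$snp_id[j], " missing from reference-allele file")
      aa <- ref$allele_a[k]; bb <- ref$allele_b[k]
    } else {
      alleles <- unique(obs)
      if (length(alleles) > 2) {
        stop("more than two alleles at SNP ", map$snp_id[j])
      }
      if (length(alleles) == 0) alleles <- c("A", "B")
      if (length(alleles) == 1) alleles <- c(alleles, if (alleles == "B") "A" else "B")
      counts <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
      # major allele is allele_a; tie broken to first observed (alleles[1])
      if (counts[2] > counts[1]) alleles <- rev(alleles)
      aa <- alleles[1]; bb <- alleles[2]
    }
    bad <- !miss & !((x1 %in% c(aa, bb)) & (x2 %in% c(aa, bb)))
    if (any(bad)) {
      stop("parse error in .ped line ", which(bad)[1], ": unexpected allele at SNP ",
           map$snp_id[j])
    }
    g <- (x1 == bb) + (x2 == bb)
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
    allele_a[j] <- aa
    allele_b[j] <- bb
  }

  mk <- marker_map(map$snp_id, map$chromosome, map$bp_position,
                   allele_a, allele_b)
  ord <- match(mk$snp_id, map$snp_id)
  genotype_matrix(geno[, ord, drop = FALSE], mk, ids)
}

#' Write genotypes as PLINK text files
#'
#' Emits `<prefix>.ped`, `<prefix>.map` and a `<prefix>.ref` companion file
#' recording the allele orientation, so that
#' `read_plink_text(write_plink_text(gm))` round-trips losslessly (coding,
#' missingness and marker order).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_plink_text <- function(gm, prefix) {
  mk <- gm$markers
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  ref_path <- paste0(prefix, ".ref")
  cm <- if (!is.null(mk$morgan_position)) 100 * mk$morgan_position else rep(0, nrow(mk))
  ok <- tryCatch({
    writeLines(paste(mk$chromosome, mk$snp_id, cm, mk$bp_position), map_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", map_path)
  g <- gm$genotypes
  n <- nrow(g); m <- ncol(g)
  lines <- character(n)
  A <- matrix(rep(mk$allele_a, each = n), n, m)
  B <- matrix(rep(mk$allele_b, each = n), n, m)
  al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, B, A))
  al2 <- ifelse(is.na(g), "0", ifelse(g == 2, B, A))
  for (i in seq_len(n)) {
    gl <- as.vector(rbind(al1[i, ], al2[i, ]))
    lines[i] <- paste(c("FAM", gm$sample_ids[i], "0", "0", "0", "-9", gl),
                      collapse = " ")
  }
  writeLines(lines, ped_path)
  write.table(data.frame(snp_id = mk$snp_id, allele_a = mk$allele_a,
                         allele_b = mk$allele_b),
              ref_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, ref = ref_path))
}

#' Read diploid genotypes from a VCF file (convenience)
#'
#' Minimal reader for the GT field of a diploid VCF; requires the `vcfR`
#' package. The REF allele becomes `allele_a`.
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF.
#' @return A [genotype_matrix()]; phase in the GT field is ignored.
#' @export
read_vcf_genotypes <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_genotypes requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  count_b <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), 0L))
  }
  geno <- t(apply(gt, 1, count_b))
  ids <- colnames(gt)
  snp_id <- fix[, "ID"]
  snp_id[is.na(snp_id) | snp_id == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp_id) | snp_id == "."]
  mk <- marker_map(snp_id, fix[, "CHROM"], as.integer(fix[, "POS"]),
                   fix[, "REF"], fix[, "ALT"])
  ord <- match(mk$snp_id, snp_id)
  genotype_matrix(t(geno)[, ord, drop = FALSE], mk, ids)
}

#' Mask genotypes down to a low-density panel
#'
#' Emulates genotyping a sample at panel SNPs only: genotypes at all
#' non-panel SNPs are set to missing, panel SNPs are untouched and the marker
#' map keeps all columns. Phased haplotypes (truth phase) are dropped from
#' the masked copy, since a panel-genotyped individual has none.
#'
#' @param gm a [genotype_matrix()].
#' @param panel an `ldp_panel` object or a character vector of SNP ids.
#' @return The masked `genotype_matrix`.
#' @export
mask_to_panel <- function(gm, panel) {
  ids <- panel_snp_ids(panel)
  idx <- match(ids, gm$markers$snp_id)
  if (anyNA(idx)) {
    stop("panel SNP id(s) not in marker map: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  }
  g <- gm$genotypes
  keep <- logical(ncol(g))
  keep[idx] <- TRUE
  g[, !keep] <- NA_integer_
  genotype_matrix(g, gm$markers, gm$sample_ids)
}

#' Randomly partition samples into labelled sets
#'
#' Uniform random partition, reproducible given `seed`. The specification is
#' a named numeric vector processed left to right: entries > 1 are absolute
#' set sizes drawn first; entries <= 1 are fractions of the *remaining*
#' samples and must sum to 1. Fractional sizes are rounded to the nearest
#' integer, with the remainder going to the last fractional set (so 653
#' remaining samples at 75%/25% give 490 and 163).
#'
#' @param sample_ids character vector of sample ids.
#' @param spec named numeric vector, e.g. `c(A = 200, B = 0.75, C = 0.25)`.
#' @param seed integer seed.
#' @return A list of class `sample_split` with elements `labels` (named
#'   character vector sample_id -> set label), `sets` (list of id vectors),
#'   `sizes` and `seed`.
#' @export
split_samples <- function(sample_ids, spec, seed) {
  if (is.null(names(spec)) || any(!nzchar(names(spec)))) {
    stop("spec must be a named numeric vector")
  }
  abs_spec <- spec[spec > 1]
  frac_spec <- spec[spec <= 1]
  if (length(frac_spec) && abs(sum(frac_spec) - 1) > 1e-8) {
    stop("fractional set sizes must sum to 1 (got ", sum(frac_spec), ")")
  }
  n <- length(sample_ids)
  if (sum(abs_spec) > n) stop("requested absolute sizes exceed sample count")
  perm <- with_seed(seed, sample(sample_ids))
  sizes <- integer(0)
  for (nm in names(abs_spec)) sizes[nm] <- as.integer(abs_spec[nm])
  rem <- n - sum(sizes)
  if (length(frac_spec)) {
    fs <- round(rem * frac_spec)
    fs[length(fs)] <- rem - sum(fs[-length(fs)])
    for (nm in names(frac_spec)) sizes[nm] <- as.integer(fs[nm])
  }
  if (sum(sizes) != n) stop("split sizes do not cover all samples")
  labels <- rep(names(sizes), times = sizes)
  names(labels) <- perm
  labels <- labels[sample_ids]  # report in input order
  sets <- split(names(labels), factor(labels, levels = names(sizes)))
  structure(list(labels = labels, sets = sets, sizes = sizes, seed = seed),
            class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat("sample_split (seed ", x$seed, "): ",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read / write panel SNP-id files
#'
#' Panels are stored as one SNP id per line, with a JSON sidecar
#' (`<path>.json`) recording method, target size, spacing and seed.
#'
#' @param panel an `ldp_panel` object.
#' @param path output text file path.
#' @return `write_panel` invisibly returns `path`; `read_panel` returns an
#'   `ldp_panel` (metadata restored from the sidecar when present).
#' @export
write_panel <- function(panel, path) {
  writeLines(panel_snp_ids(panel), path)
  meta <- panel[setdiff(names(panel), "per_chromosome")]
  meta$per_chromosome <- lapply(panel$per_chromosome, identity)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta$per_chromosome <- lapply(meta$per_chromosome, as.character)
    structure(meta, class = "ldp_panel")
  } else {
    structure(list(method = "unknown", target_total = length(ids),
                   per_chromosome = list(unknown = ids),
                   coordinate_system = "bp"),
              class = "ldp_panel")
  }
}
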