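#' Experiment configuration
#'
#' Validates a flat key/value experiment configuration; unknown keys are
#' rejected. Recognised keys:
#' \describe{
#'   \item{sim}{a [sim_config()] (or `ped`/`map` paths for real data).}
#'   \item{ped, map}{PLINK text paths, alternative to `sim`.}
#'   \item{split}{named split spec for [split_samples()]; default
#'     `c(A = 200, B = 0.75, C = 0.25)`.}
#'   \item{methods}{subset of `c("bpeq", "bpmaf", "ldumaf")`.}
#'   \item{panel_sizes}{integer vector of panel sizes to test.}
#'   \item{engines}{subset of `c("random", "hmm")`; both by default.}
#'   \item{ne}{effective population size for density reporting and the HMM
#'     switch rate (default 150).}
#'   \item{genome_morgans}{genome genetic length for density reporting.}
#'   \item{qc}{list(min_call_rate, min_maf).}
#'   \item{hmm}{list(K, err) HMM engine settings.}
#'   \item{ga}{GA parameter overrides for [select_optimized()].}
#'   \item{half_sib}{list(n, size): half-sib families appended to
#'     population 2 (between-population experiments only).}
#'   \item{seed}{master seed; every stage derives its seed from it.}
#'   \item{out_dir}{optional directory for report files.}
#' }
#'
#' @param ... configuration entries.
#' @return A validated list of class `ldp_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(...)
  allowed <- c("sim", "ped", "map", "split", "methods", "panel_sizes",
               "engines", "ne", "genome_morgans", "qc", "hmm", "ga",
               "half_sib", "seed", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(split = c(A = 200, B = 0.75, C = 0.25),
                   methods = c("bpeq", "bpmaf", "ldumaf"),
                   engines = c("random", "hmm"),
                   ne = 150, qc = list(min_call_rate = 0.95, min_maf = 0.01),
                   hmm = list(K = 60, err = 0.002), ga = list(),
                   seed = 1, out_dir = NULL)
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$sim) && (is.null(cfg$ped) || is.null(cfg$map))) {
    stop("config error: provide either `sim` or `ped`+`map`")
  }
  if (is.null(cfg$panel_sizes)) stop("config error: panel_sizes required")
  bad <- setdiff(cfg$methods, c("bpeq", "bpmaf", "ldumaf"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$engines, c("random", "hmm"))
  if (length(bad)) stop("unknown engine(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$genome_morgans)) {
    cfg$genome_morgans <- if (!is.null(cfg$sim)) sum(cfg$sim$chrom_morgans) else NA_real_
  }
  class(cfg) <- "ldp_config"
  cfg
}

load_experiment_population <- function(cfg, log) {
  if (!is.null(cfg$sim)) {
    pop <- simulate_population(cfg$sim)
    log("simulate", sprintf("%d samples, %d SNPs",
                            length(pop$sample_ids), nrow(pop$markers)))
  } else {
    pop <- read_plink_text(cfg$ped, cfg$map)
    log("load", sprintf("%d samples, %d SNPs from %s",
                        length(pop$sample_ids), nrow(pop$markers), cfg$ped))
  }
  pop
}

prepare_design <- function(cfg, pop, design_ids, log) {
  designA <- subset_gm(pop, samples = design_ids)
  qc <- filter_snps(designA, cfg$qc$min_call_rate, cfg$qc$min_maf)
  log("qc", sprintf("%d of %d SNPs retained on design set",
                    nrow(qc$gm$markers), nrow(pop$markers)))
  keep <- qc$gm$markers$snp_id
  pop_qc <- subset_gm(pop, snps = keep)
  mafs <- maf_vector(qc$gm)
  ldu_maps <- NULL
  if ("ldumaf" %in% cfg$methods) {
    ldu_maps <- lapply(
      setNames(nm = unique(pop_qc$markers$chromosome)),
      function(ch) build_ldu_map(qc$gm, chromosome = ch)
    )
    log("ldmap", sprintf("LDU maps built for %d chromosome(s)", length(ldu_maps)))
  }
  list(pop_qc = pop_qc, qc_report = qc$report, mafs = mafs,
       ldu_maps = ldu_maps)
}

design_all_panels <- function(cfg, des, log) {
  panels <- list()
  for (method in cfg$methods) {
    for (size in cfg$panel_sizes) {
      key <- paste(method, size, sep = "_")
      panels[[key]] <- design_panel(des$pop_qc$markers, des$mafs, method,
                                    size, ldu_maps = des$ldu_maps,
                                    ga_params = cfg$ga, seed = cfg$seed + size)
      log("select", sprintf("%s size %d: %d SNPs selected", method, size,
                            length(panel_snp_ids(panels[[key]]))))
    }
  }
  panels
}

impute_and_score <- function(cfg, panels, test_pop, ref_pop, log,
                             assessment = "within") {
  grid <- list(); reports <- list()
  ref_freqs <- allele_freqs(ref_pop)
  for (key in names(panels)) {
    panel <- panels[[key]]
    masked <- mask_to_panel(test_pop, panel)
    for (engine in cfg$engines) {
      res <- if (engine == "random") {
        impute_random(masked, ref_freqs, seed = cfg$seed + 1000)
      } else {
        impute_hmm(masked, ref_pop, markers = masked$markers,
                   K = cfg$hmm$K, err = cfg$hmm$err, ne = cfg$ne,
                   seed = cfg$seed + 2000)
      }
      rep_ <- build_accuracy_report(test_pop, res, ref_freqs = ref_freqs)
      rkey <- paste(assessment, key, engine, sep = "_")
      reports[[rkey]] <- rep_
      size <- panel$target_total
      grid[[rkey]] <- data.frame(
        assessment = assessment, method = panel$method, panel_size = size,
        density_ne_morgan = if (is.na(cfg$genome_morgans)) NA_real_ else
          panel_density_ne_per_morgan(size, cfg$genome_morgans, cfg$ne),
        engine = engine,
        mean_snp_prop_correct = rep_$summary["snp_proportion_correct", "mean"],
        mean_snp_correlation = rep_$summary["snp_correlation", "mean"],
        mean_snp_adjusted = rep_$summary["snp_adjusted", "mean"],
        mean_ind_prop_correct = rep_$summary["individual_proportion_correct", "mean"],
        mean_ind_correlation = rep_$summary["individual_correlation", "mean"],
        stringsAsFactors = FALSE)
      log("impute", sprintf("%s %s %s: mean per-SNP accuracy %.3f",
                            assessment, key, engine,
                            grid[[rkey]]$mean_snp_prop_correct))
    }
  }
  list(grid = do.call(rbind, grid), reports = reports)
}

#' Run the within-population panel-design and imputation experiment
#'
#' Executes the full data flow on one population: random split into a
#' panel-design set (A), a reference set (B) and a test set (C); SNP QC on
#' A; LDU maps from A when needed; panel selection per method and density
#' using A; masking of C to each panel; imputation of C from B with the
#' random baseline and the haplotype-copying HMM; and accuracy reports for
#' every cell of the method x density x engine grid.
#'
#' @param config an [experiment_config()].
#' @return A list with `grid` (summary data.frame), `reports` (named list of
#'   `accuracy_report`s), `panels`, `qc_report`, `log` (one line per stage)
#'   and `config`. When `config$out_dir` is set the grid, QC report and
#'   per-cell reports are also written there.
#' @export
run_within_population_experiment <- function(config) {
  stopifnot(inherits(config, "ldp_config"))
  log_lines <- character(0)
  log <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  log("config", sprintf("seed %d, methods %s, sizes %s", config$seed,
                        paste(config$methods, collapse = "/"),
                        paste(config$panel_sizes, collapse = "/")))
  pop <- load_experiment_population(config, log)
  split <- split_samples(pop$sample_ids, config$split, seed = config$seed)
  log("split", paste(sprintf("%s=%d", names(split$sizes), split$sizes),
                     collapse = ", "))
  des <- prepare_design(config, pop, split$sets$A, log)
  panels <- design_all_panels(config, des, log)
  refB <- subset_gm(des$pop_qc, samples = split$sets$B)
  testC <- subset_gm(des$pop_qc, samples = split$sets$C)
  scored <- impute_and_score(config, panels, testC, refB, log)
  out <- list(grid = scored$grid, reports = scored$reports, panels = panels,
              qc_report = des$qc_report, split = split, log = log_lines,
              config = config)
  if (!is.null(config$out_dir)) write_experiment_outputs(out, config$out_dir)
  out
}

#' Run the between-population imputation experiment
#'
#' Panels are always selected from population 1's design set (A). Three
#' assessments are produced for each panel and engine: `within`
#' (population-1 test set C imputed from reference set B), `between1` (the
#' whole of population 2 imputed from population-1 set B) and `between2`
#' (population 2 split 75/25 into sets D and E; E imputed from D). With
#' `config$half_sib` set, half-sib families are appended to population 2
#' before the D/E split, raising its internal relatedness.
#'
#' @param config an [experiment_config()] whose `sim` has
#'   `split_generations`/`migration_rate` set (or which supplies two
#'   populations via `sim = list(pop1 = , pop2 = )`).
#' @return As [run_within_population_experiment()], with an `assessment`
#'   column distinguishing the three analyses.
#' @export
run_between_population_experiment <- function(config) {
  stopifnot(inherits(config, "ldp_config"))
  log_lines <- character(0)
  log <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  if (inherits(config$sim, "sim_config")) {
    pops <- simulate_split_populations(config$sim)
    log("simulate", sprintf("two populations (%d + %d samples), freq corr %.3f",
                            length(pops$pop1$sample_ids),
                            length(pops$pop2$sample_ids),
                            pops$freq_correlation))
  } else if (is.list(config$sim) && inherits(config$sim$pop1, "genotype_matrix") &&
             inherits(config$sim$pop2, "genotype_matrix")) {
    pops <- config$sim
  } else {
    stop("config error: between-population experiment needs a split sim_config ",
         "or explicit pop1/pop2 genotype matrices")
  }
  pop1 <- pops$pop1
  pop2 <- pops$pop2
  if (!is.null(config$half_sib)) {
    pop2 <- add_half_sib_structure(pop2, config$half_sib,
                                   seed = config$seed + 7)
    log("half_sib", sprintf("appended %d half-sib offspring",
                            length(pop2$sample_ids) - length(pops$pop2$sample_ids)))
  }
  split1 <- split_samples(pop1$sample_ids, config$split, seed = config$seed)
  des <- prepare_design(config, pop1, split1$sets$A, log)
  panels <- design_all_panels(config, des, log)
  pop2_qc <- subset_gm(pop2, snps = des$pop_qc$markers$snp_id)
  refB <- subset_gm(des$pop_qc, samples = split1$sets$B)
  testC <- subset_gm(des$pop_qc, samples = split1$sets$C)
  split2 <- split_samples(pop2_qc$sample_ids, c(D = 0.75, E = 0.25),
                          seed = config$seed + 13)
  log("split", sprintf("pop2: D=%d, E=%d", split2$sizes["D"], split2$sizes["E"]))
  refD <- subset_gm(pop2_qc, samples = split2$sets$D)
  testE <- subset_gm(pop2_qc, samples = split2$sets$E)

  s_within <- impute_and_score(config, panels, testC, refB, log, "within")
  s_b1 <- impute_and_score(config, panels, pop2_qc, refB, log, "between1")
  s_b2 <- impute_and_score(config, panels, testE, refD, log, "between2")
  out <- list(grid = rbind(s_within$grid, s_b1$grid, s_b2$grid),
              reports = c(s_within$reports, s_b1$reports, s_b2$reports),
              panels = panels, qc_report = des$qc_report,
              freq_correlation = if (!is.null(pops$freq_correlation))
                pops$freq_correlation else NA_real_,
              log = log_lines, config = config)
  if (!is.null(config$out_dir)) write_experiment_outputs(out, config$out_dir)
  out
}

write_experiment_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(out$grid, file.path(dir, "grid_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_qc_report(out$qc_report, file.path(dir, "qc_report.tsv"))
  for (key in names(out$reports)) {
    write_accuracy_report(out$reports[[key]], file.path(dir, key))
  }
  for (key in names(out$panels)) {
    write_panel(out$panels[[key]], file.path(dir, paste0("panel_", key, ".txt")))
  }
  writeLines(out$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
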