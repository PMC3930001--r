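#!/usr/bin/env Rscript
# Step 4: the within-population imputation grid.
#
# For each selection method and density, set C is masked to the panel and
# imputed from set B with both engines (random baseline and the
# haplotype-copying HMM); accuracy is summarised per SNP and per individual.
# To keep the run in minutes this driver evaluates the three densities
# bracketing the study's headline (0.24, 0.48 and 1.44 Ne/Morgan); edit
# `panel_sizes` for the full sweep. Outputs under results/within/.

library(ldpanel)

cfg <- experiment_config(
  sim = sim_config(seed = 2026),
  methods = c("bpeq", "bpmaf", "ldumaf"),
  panel_sizes = c(36, 72, 216),
  genome_morgans = 1,
  seed = 2026,
  out_dir = "results/within"
)
out <- run_within_population_experiment(cfg)
cat(paste(out$log, collapse = "\n"), "\n")
print(out$grid[, c("method", "panel_size", "density_ne_morgan", "engine",
                   "mean_snp_prop_correct", "mean_snp_correlation")],
      row.names = FALSE, digits = 3)
cat("done: results/within/\n")
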