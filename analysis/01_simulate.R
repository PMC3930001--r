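#!/usr/bin/env Rscript
# Step 1: simulate the study populations.
#
# Two Thoroughbred-like cohorts are generated: a "UK-like" population of 853
# samples used for the within-population panel-design experiments, and a
# pair of recently split populations (853 + 348 samples, 5 generations of
# separation with weak migration) used for the between-population transfer
# experiment. Truth bundles (PLINK text, phased haplotypes, Morgan map,
# config echo) go to results/sim/.

library(ldpanel)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
seed <- 2026

cfg_uk <- sim_config(seed = seed)  # Ne 150, 28 founders, 30 generations,
                                   # 1 Morgan, ~1300 chip-ascertained SNPs
pop_uk <- simulate_population(cfg_uk)
print(pop_uk)
cat(sprintf("mean MAF %.3f | median pairwise spacing %.0f kb\n",
            mean(maf_vector(pop_uk)),
            median(diff(pop_uk$markers$bp_position)) / 1000))
write_truth_bundle(pop_uk, "results/sim/uk_like", cfg_uk)

cfg_split <- sim_config(seed = seed + 1, n_samples2 = 348,
                        split_generations = 5, migration_rate = 0.05)
pops <- simulate_split_populations(cfg_split)
cat(sprintf("split populations: allele-frequency correlation %.3f\n",
            pops$freq_correlation))
write_truth_bundle(pops$pop1, "results/sim/split_pop1", cfg_split)
write_truth_bundle(pops$pop2, "results/sim/split_pop2")

cat("done: results/sim/\n")
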