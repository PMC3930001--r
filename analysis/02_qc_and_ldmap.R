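#!/usr/bin/env Rscript
# Step 2: sample split, SNP quality control and the LD-unit map.
#
# The 853 simulated samples are split 200 / 490 / 163 into the panel-design
# set (A), the imputation reference (B) and the test set (C). QC (call rate
# >= 95%, MAF >= 0.01) runs on set A only, and the LDU map is built from
# set A genotypes. Outputs: results/qc_report.tsv, results/ldu_map.tsv.

library(ldpanel)

pop <- read_plink_text("results/sim/uk_like.ped", "results/sim/uk_like.map")
sp <- split_samples(pop$sample_ids, c(A = 200, B = 0.75, C = 0.25),
                    seed = 2026)
print(sp)
A <- subset_gm(pop, samples = sp$sets$A)
qc <- filter_snps(A)
cat(sprintf("QC: %d of %d SNPs retained (%.1f%% excluded)\n",
            nrow(qc$gm$markers), nrow(pop$markers),
            100 * mean(qc$report$excluded)))
write_qc_report(qc$report, "results/qc_report.tsv")

map <- build_ldu_map(qc$gm)
print(map)
write_ldu_map(map, "results/ldu_map.tsv")
cat("done: results/qc_report.tsv, results/ldu_map.tsv\n")
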