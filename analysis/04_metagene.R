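#!/usr/bin/env Rscript
# Step 4 — metagene profiling of the repressed genes.
#
# Coverage tracks are simulated for the repressed gene set (uniform body
# coverage; the perturbed condition at half the level), spike-scaled, and
# averaged into body +/- 3 kb flank profiles. The 5'/3' ratio-of-ratios
# asks whether the loss is body-uniform (initiation-level repression) or
# 3'-biased (elongation-level): a programmed body-wide halving must give a
# ratio-of-ratios of 1.

library(nascentshift)

ann <- read_annotation("results/annotation.tsv", "tsv")
res <- read_results_table("results/deg_table.tsv")

repressed <- res$gene[res$call == "down" &
                        res$class %in% c("protein_coding", "histone")]
genes <- ann[ann$feature_id %in% repressed & ann$length_bp >= 100, ]
cat("profiling", nrow(genes), "repressed genes\n")

cov <- simulate_coverage(genes, "uniform", level = 5,
                         condition_factors = c(ctrl = 1, ir = 0.5))
write_bedgraph(cov$ctrl, "results/coverage_ctrl.bedgraph")
write_bedgraph(cov$ir, "results/coverage_ir.bedgraph")

# spike-in-derived factors for the tracks (here 1: equal simulated depth)
track_ctrl <- scale_coverage(read_bedgraph("results/coverage_ctrl.bedgraph"), 1)
track_ir <- scale_coverage(read_bedgraph("results/coverage_ir.bedgraph"), 1)

prof_ctrl <- build_metagene(track_ctrl, genes, flank_bp = 3000,
                            body_bins = 100, flank_bins = 60, label = "ctrl")
prof_ir <- build_metagene(track_ir, genes, flank_bp = 3000,
                          body_bins = 100, flank_bins = 60, label = "ir")
print(prof_ctrl)
print(prof_ir)

write_results_table(
  data.frame(bin = seq_along(prof_ctrl$values),
             bin_type = prof_ctrl$bin_type,
             ctrl = prof_ctrl$values, ir = prof_ir$values),
  "results/metagene_profile.tsv")

r <- five_three_ratio(prof_ctrl, prof_ir)
print(r)
write_results_table(
  data.frame(quantity = c("r5_ctrl", "r3_ctrl", "r5_ir", "r3_ir",
                          "ratio_of_ratios"),
             value = c(r$r5_ref, r$r3_ref, r$r5_alt, r$r3_alt,
                       r$ratio_of_ratios)),
  "results/five_three_ratio.tsv")
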