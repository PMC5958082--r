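#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Emulates the cross-sectional design this pipeline targets: four
# phenotypes (43 HC, 35 ADU, 26 ADT, 14 ID samples), 4000 genes and 400
# miRNAs on the log2 scale, 40% of genes differentially expressed with a
# pattern mix dominated by the same-direction clusters, 5 planted
# anti-correlated miRNA regulators and 5 planted TFs (50 targets each,
# 80% drawn from their planted cluster) plus 20 decoys per kind, and a
# 16-sample qPCR validation panel. Everything downstream reads the files
# written here; the planted truth is saved alongside for evaluation.

library(rewiremir)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260927)
sim <- simulate_expression(cfg)
ts <- simulate_target_sets(sim, cfg)
sim$truth <- ts$truth
qpcr <- simulate_qpcr(sim, cfg)

write_expression(sim$mrna, file.path(out, "mrna.tsv"))
write_expression(sim$mirna, file.path(out, "mirna.tsv"))
write_design(sim$design, file.path(out, "design.tsv"))
write_gmt(ts$mirna_sets, file.path(out, "mirna_targets.gmt"))
write_gmt(ts$tf_sets, file.path(out, "tf_targets.gmt"))
write.table(qpcr, file.path(out, "qpcr.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_truth(sim$truth, file.path(out, "truth.json"))

n_de <- sum(!is.na(sim$truth$gene_pattern))
cat(sprintf("simulated %d genes (%d with planted effects), %d miRNAs,\n",
            nrow(sim$mrna), n_de, nrow(sim$mirna)))
cat(sprintf("%d samples; %d planted regulators per kind; wrote %s/\n",
            ncol(sim$mrna), cfg$n_regulators_per_kind, out))
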