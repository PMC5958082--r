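#!/usr/bin/env Rscript
# Step 3 — cross-phenotype overlap statistics and dynamic clustering.
#
# Hypergeometric overlap of the three DEG lists (universe = genes
# tested), the 3-way Venn partition, and the assignment of every
# union DEG to its 3-letter direction pattern with UUu/DDd attenuation
# sub-clusters. Writes results/overlaps/ and results/patterns/ and
# prints the cluster census against the planted one.

library(rewiremir)

de_dir <- "results/de"
dir.create("results/overlaps", recursive = TRUE, showWarnings = FALSE)
dir.create("results/patterns", recursive = TRUE, showWarnings = FALSE)

de <- lapply(c(ADU = "ADU", ADT = "ADT", ID = "ID"), function(ph)
  read.delim(file.path(de_dir, sprintf("de_mrna_%s.tsv", ph)),
             stringsAsFactors = FALSE))
degs <- lapply(de, function(d)
  d$feature_id[d$q_value <= 0.05])
universe_n <- nrow(de$ADU)

ov <- pairwise_overlaps(degs, universe = universe_n)
write.table(ov, "results/overlaps/pairwise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
venn <- venn_partition(degs)
jsonlite::write_json(as.list(venn), "results/overlaps/venn.json",
                     auto_unbox = TRUE)
cat("pairwise DEG overlaps (p upper-tail hypergeometric):\n")
print(ov[, c("set_a", "set_b", "overlap_count", "percent_of_smaller",
             "p_value")], row.names = FALSE)

union_genes <- union_degs(degs)
lfc <- vapply(de, function(d)
  setNames(d$log2fc, d$feature_id)[union_genes],
  numeric(length(union_genes)))
dimnames(lfc) <- list(union_genes, names(de))
assignments <- assign_patterns(lfc)
write.table(assignments, "results/patterns/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
census <- cluster_census(assignments)
jsonlite::write_json(census, "results/patterns/census.json", digits = NA)
cat(sprintf("\n%d union DEGs classified into the 8 direction clusters:\n",
            nrow(assignments)))
print(census, row.names = FALSE)
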