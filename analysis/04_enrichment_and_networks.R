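#!/usr/bin/env Rscript
# Step 4 — regulator enrichment, miRNA direction consistency, networks.
#
# Fisher exact target-set enrichment of every miRNA and TF set against
# every (sub-)cluster at uncorrected p < 0.01, direction-consistency
# classification of enriched miRNAs against their cluster pattern, and
# per-cluster co-regulatory network assembly (family-collapsed miRNAs +
# TFs joined to in-cluster targets), exported as SIF and GraphML under
# results/networks/.

library(rewiremir)

dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)
dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)

mrna <- read_expression("results/data/mrna.tsv", "mRNA")
assignments <- read.delim("results/patterns/assignments.tsv",
                          stringsAsFactors = FALSE)
mirna_sets <- read_gmt("results/data/mirna_targets.gmt", "miRNA")
tf_sets <- read_gmt("results/data/tf_targets.gmt", "TF")

clusters <- cluster_members(assignments, use_subpattern = TRUE)
enr <- enrich_all(clusters, list(mirna_sets, tf_sets),
                  universe = rownames(mrna), keep_all = TRUE)
write.table(enr, "results/enrichment/all_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- enr[enr$significant, , drop = FALSE]
cat(sprintf("%d of %d (cluster, set) tests enriched at p < 0.01:\n",
            nrow(sig), nrow(enr)))
print(sig[, c("cluster_id", "regulator", "kind", "k", "K", "p_value")],
      row.names = FALSE)

# direction consistency of enriched miRNAs with expression profiles
mirna_de <- lapply(c(ADU = "ADU", ADT = "ADT", ID = "ID"), function(ph)
  read.delim(sprintf("results/de/de_mirna_%s.tsv", ph),
             stringsAsFactors = FALSE))
mir_sig <- sig[sig$kind == "miRNA" &
                 sig$regulator %in% mirna_de$ADU$feature_id, ,
               drop = FALSE]
if (nrow(mir_sig) > 0) {
  cons <- do.call(rbind, lapply(seq_len(nrow(mir_sig)), function(i) {
    m <- mir_sig$regulator[i]
    lfc <- vapply(mirna_de, function(d)
      d$log2fc[match(m, d$feature_id)], numeric(1))
    direction_consistency(m, lfc, mir_sig$cluster_id[i])
  }))
  write.table(cons, "results/enrichment/mirna_consistency.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\nmiRNA direction consistency vs their enriched cluster:\n")
  print(cons[, c("mirna_id", "cluster_pattern", "category")],
        row.names = FALSE)
}

for (cl in unique(sig$cluster_id)) {
  net <- suppressWarnings(build_network(
    clusters[[cl]], sig[sig$cluster_id == cl, , drop = FALSE],
    list(mirna_sets, tf_sets), cluster_id = cl))
  export_network(net, sprintf("results/networks/%s.sif", cl), "SIF")
  export_network(net, sprintf("results/networks/%s.graphml", cl),
                 "GraphML")
  s <- network_summary(net)
  cat(sprintf(
    "network %s: %d genes, %d miRNAs, %d TFs, %d edges, %d component(s)\n",
    cl, s$n_gene, s$n_mirna, s$n_tf, s$n_edges, s$n_components))
}
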