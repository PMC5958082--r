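#!/usr/bin/env Rscript
# Step 5 — qPCR validation of the array fold changes.
#
# Delta-delta-Ct fold changes for the validation panel (ADT vs HC,
# reference-normalized Ct values) and cross-platform concordance: a
# panel feature is concordant when its array log2 fold change and its
# qPCR fold change agree in sign.

library(rewiremir)

dir.create("results/qpcr", recursive = TRUE, showWarnings = FALSE)

qpcr <- read.delim("results/data/qpcr.tsv", stringsAsFactors = FALSE)
de_adt <- read.delim("results/de/de_mrna_ADT.tsv",
                     stringsAsFactors = FALSE)

fc <- ddct_fold_change(qpcr, "ADT")
write.table(fc, "results/qpcr/fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

array_lfc <- setNames(de_adt$log2fc, de_adt$feature_id)
conc <- platform_concordance(array_lfc[fc$feature_id],
                             setNames(fc$fold_change, fc$feature_id))
jsonlite::write_json(list(n_concordant = conc$n_concordant,
                          n_total = conc$n_total),
                     "results/qpcr/concordance.json", auto_unbox = TRUE)
cat(sprintf("qPCR concordance: %d of %d panel features change in the same
direction on both platforms\n", conc$n_concordant, conc$n_total))
print(fc[, c("feature_id", "ddct", "fold_change")], row.names = FALSE)
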