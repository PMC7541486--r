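#!/usr/bin/env Rscript
# Cell-type composition testing: within-sample subtype proportions, the
# sample-label permutation test, and the ordinal categories (p used as a
# continuous measure, not a binary verdict).

suppressMessages(library(episcope))
dir.create("results", showWarnings = FALSE)

data <- load_counts("results/cohort/matrix.mtx", "results/cohort/genes.tsv",
                    "results/cohort/metadata.tsv")
ct <- composition_test(data, n_perm = 10000, seed = 20240917L)
cat_tab <- categorize_composition(ct, class_partition(data))

write.table(ct$proportions, "results/composition_proportions.tsv",
            sep = "\t", quote = FALSE)
write.table(cat_tab[order(cat_tab$p), ], "results/category_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("smallest composition p values:\n")
print(head(cat_tab[order(cat_tab$p), ], 4), row.names = FALSE)
cat("wrote results/category_composition.tsv\n")
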