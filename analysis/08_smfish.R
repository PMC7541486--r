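#!/usr/bin/env Rscript
# smFISH intensity analysis: log2 transform, quantile normalization of the
# reference (VIP-like) channel across sections, the reference-ratio
# correction of the target channel, and the one-sided group comparisons.

suppressMessages(library(episcope))
dir.create("results", showWarnings = FALSE)

fish <- read.table("results/cohort/smfish_intensities.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
norm <- normalize_target(fish)
write.table(norm, "results/smfish_normalized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

welch <- compare_groups(norm$log2_target_normalized, norm$group,
                        "welch", "less")
mw <- compare_groups(norm$log2_target_normalized, norm$group,
                     "mann_whitney", "less")
med <- tapply(norm$log2_target_normalized, norm$group, median)

cat(sprintf("cells: %d control, %d case (excluded: %d)\n",
            sum(norm$group == "control"), sum(norm$group == "case"),
            nrow(attr(norm, "excluded"))))
cat(sprintf("median log2 normalized target: control %.2f, case %.2f\n",
            med["control"], med["case"]))
cat(sprintf("Welch one-sided (case < control): p = %.3g\n", welch$p))
cat(sprintf("Mann-Whitney one-sided:           p = %.3g\n", mw$p))
cat("wrote results/smfish_normalized.tsv\n")
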