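#!/usr/bin/env Rscript
# Aggregate the six ordinal metrics (expression similarity, composition,
# GO-term count, GWAS enrichment, epilepsy-gene enrichment, DE-gene count)
# into the weighted impact score and rank subtypes within their class.

suppressMessages(library(episcope))

data <- load_counts("results/cohort/matrix.mtx", "results/cohort/genes.tsv",
                    "results/cohort/metadata.tsv")
cls <- class_partition(data)
subtypes <- sort(unique(data$meta$level4))

read_cat <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  r <- setNames(rep(0L, length(subtypes)), subtypes)
  r[tab$subtype] <- tab$category
  r
}
sim_tab <- read.table("results/similarity_scores.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
sim_rank <- setNames(rep(0L, length(subtypes)), subtypes)
sim_rank[sim_tab$subtype] <- sim_tab$category

ranks <- cbind(similarity = sim_rank,
               composition = read_cat("results/category_composition.tsv"),
               go_count = read_cat("results/category_go_count.tsv"),
               gwas = read_cat("results/category_gwas.tsv"),
               epilepsy = read_cat("results/category_epilepsy.tsv"),
               de_count = read_cat("results/category_de_count.tsv"))

impact <- aggregate_impact(ranks, cls)
impact <- impact[order(impact$class, impact$class_rank), ]
write.table(impact, "results/impact_score.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("impact ranking (top 3 per class):\n")
for (k in unique(impact$class)) {
  print(head(impact[impact$class == k, ], 3), row.names = FALSE)
}
cat("wrote results/impact_score.tsv\n")
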