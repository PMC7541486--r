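#!/usr/bin/env Rscript
# GO-term over-representation per subtype, the autopsy-gene filter, term
# clustering within subtypes, the cross-subtype collapse by co-clustering
# disagreement, the min-log-p heatmap grouping, the (subtype, cluster) pair
# embedding, the weighted-Jaccard subtype similarity, and the DE-count-
# adjusted GO-count residual metric.

suppressMessages(library(episcope))
dir.create("results", showWarnings = FALSE)

data <- load_counts("results/cohort/matrix.mtx", "results/cohort/genes.tsv",
                    "results/cohort/metadata.tsv")
gene_sets <- read_gmt("results/cohort/gene_sets.gmt")
autopsy <- read_gene_list("results/cohort/autopsy_genes.txt")
de_genes <- read.table("results/de_genes.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
de_sets <- split(de_genes$gene, de_genes$subtype)
background <- expressed_genes(data)
cls <- class_partition(data)

terms <- go_overrepresentation(de_sets, gene_sets, background)
cat("enriched (subtype, term) pairs:", nrow(terms), "\n")
terms <- autopsy_filter(terms, autopsy)
cat("after autopsy filter:", nrow(terms), "\n")

flat <- terms[, c("subtype", "term", "namespace", "overlap", "p", "padj")]
flat$genes <- vapply(terms$genes, paste, character(1), collapse = ",")
write.table(flat, "results/go_terms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (nrow(terms) >= 2 && length(unique(terms$term)) >= 2) {
  terms <- cluster_terms_within_subtype(terms)
  pc <- collapse_terms_across_subtypes(terms)
  cat("terms collapse:", length(unique(terms$term)), "->",
      length(unique(pc$membership)), "clusters\n")
  write.table(data.frame(term = names(pc$membership),
                         cluster = pc$membership,
                         representative =
                           pc$representative[as.character(pc$membership)]),
              "results/pathway_clusters.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  hm <- heatmap_groups(pc, terms, min_group = 2)
  write.table(hm$matrix, "results/pathway_heatmap.tsv", sep = "\t",
              quote = FALSE)
  emb <- tryCatch(pair_embedding(terms, pc, seed = 20240917L),
                  error = function(e) NULL)
  if (!is.null(emb))
    write.table(emb, "results/pair_embedding.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
  ss <- tryCatch(subtype_similarity(terms), error = function(e) NULL)
  if (!is.null(ss))
    write.table(ss$similarity, "results/subtype_similarity.tsv",
                sep = "\t", quote = FALSE)
}

# GO-count metric: residuals of term counts regressed on DE-gene counts
term_counts <- table(factor(terms$subtype, names(de_sets)))
de_counts <- vapply(de_sets, length, integer(1))
go_res <- residual_metric(de_counts, as.numeric(term_counts))
go_cat <- categorize_count_residual(go_res, cls)
write.table(go_cat, "results/category_go_count.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/go_terms.tsv and pathway tables\n")
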