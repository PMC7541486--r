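#' Class partition of subtypes
#'
#' @param data an [annotated_counts()].
#' @param level subtype annotation column.
#' @return named vector subtype -> class (principal / interneuron).
#' @export
class_partition <- function(data, level = "level4") {
  m <- data$meta[!duplicated(data$meta[[level]]), ]
  setNames(m$class, m[[level]])
}

#' Run the six-metric impact pipeline on an annotated cohort
#'
#' Convenience driver over the package's stages: expression-similarity
#' scoring (joint PCA, centroid correlations, trimmed-mean/MAD baseline),
#' composition permutation testing, pseudobulk differential expression with
#' the |Z| > 3 and 5%-expression post-filters, gene-list Fisher enrichment
#' (GWAS and curated epilepsy lists), GO over-representation with the
#' autopsy filter, the two robust-regression count residuals, and the
#' weighted ordinal aggregation. Subtypes for which a metric cannot be
#' computed (no DE genes, degenerate baseline) rank 0 on that metric.
#'
#' @param data an [annotated_counts()].
#' @param gene_sets named list of term gene sets for GO testing.
#' @param gwas_genes,epilepsy_genes,autopsy_genes gene lists.
#' @param level subtype annotation column.
#' @param n_pcs principal components for the similarity stage.
#' @param min_cells minimum cells per (subtype, sample) centroid.
#' @param n_perm composition permutations.
#' @param seed integer seed.
#' @param scale total-count normalization target.
#' @return list with `similarity`, `composition`, `de` (per-subtype DE gene
#'   sets), `background`, `enrichment` (gwas/epilepsy), `terms`, `ranks`,
#'   `impact` (the aggregated score table).
#' @export
impact_pipeline <- function(data, gene_sets, gwas_genes, epilepsy_genes,
                            autopsy_genes = character(0), level = "level4",
                            n_pcs = 50L, min_cells = 5L, n_perm = 1000L,
                            seed = 1L, scale = 1e4) {
  cls <- class_partition(data, level)
  subtypes <- sort(unique(data$meta[[level]]))

  norm <- total_count_normalize(data, scale = scale)
  pca <- suppressWarnings(joint_pca(norm, n_components = n_pcs))
  cents <- subtype_sample_centroids(pca$scores, data$meta,
                                    min_cells = min_cells, level = level)
  sim <- similarity_scores(cents)
  sim_cat <- classify_similarity(sim, cls)

  comp <- composition_test(data, n_perm = n_perm, seed = seed, level = level)
  comp_cat <- categorize_composition(comp, cls)

  background <- expressed_genes(data, level = level)
  de_sets <- list(); n_cells <- integer(0)
  for (t in subtypes) {
    de <- tryCatch(pseudobulk_de(data, t, level = level),
                   error = function(e) NULL)
    if (is.null(de)) next
    de_sets[[t]] <- intersect(filter_de_genes(de, data, level = level),
                              background)
    n_cells[t] <- de$n_cells
  }

  enr <- function(lst) {
    res <- lapply(de_sets, gene_list_enrichment, gene_list = lst,
                  background = background)
    categorize_enrichment(res, cls)
  }
  gwas_cat <- enr(gwas_genes)
  epi_cat <- enr(epilepsy_genes)

  terms <- go_overrepresentation(de_sets, gene_sets, background)
  terms <- autopsy_filter(terms, autopsy_genes)
  term_counts <- table(factor(terms$subtype, names(de_sets)))

  de_counts <- vapply(de_sets, length, integer(1))
  de_res <- residual_metric(setNames(n_cells[names(de_sets)], names(de_sets)),
                            de_counts)
  de_cat <- categorize_count_residual(de_res, cls)
  go_res <- residual_metric(de_counts, as.numeric(term_counts))
  go_cat <- categorize_count_residual(go_res, cls)

  rank_of <- function(tab) {
    r <- setNames(rep(0L, length(subtypes)), subtypes)
    r[tab$subtype] <- tab$category
    r
  }
  ranks <- cbind(similarity = rank_of(sim_cat),
                 composition = rank_of(comp_cat),
                 go_count = rank_of(go_cat),
                 gwas = rank_of(gwas_cat),
                 epilepsy = rank_of(epi_cat),
                 de_count = rank_of(de_cat))
  impact <- aggregate_impact(ranks, cls)
  list(similarity = sim, similarity_category = sim_cat,
       composition = comp, composition_category = comp_cat,
       de = de_sets, background = background,
       enrichment = list(gwas = gwas_cat, epilepsy = epi_cat),
       terms = terms, de_residuals = de_res, go_residuals = go_res,
       ranks = ranks, impact = impact)
}
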