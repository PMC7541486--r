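jaccard_sim <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

jaccard_dist_matrix <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- 1 - jaccard_sim(sets[[i]], sets[[j]])
  }
  d
}

#' GO-term over-representation per subtype
#'
#' One-sided hypergeometric over-representation test of each term's gene set
#' in each subtype's DE genes against a common universe, with
#' Benjamini--Hochberg adjustment within (subtype, namespace); terms with
#' adjusted p <= `alpha` are retained. The enriched gene set of a retained
#' term is its intersection with the subtype's DE genes.
#'
#' @param de_genes_by_subtype named list: per subtype, its DE gene ids.
#' @param gene_sets named list of term gene sets (GMT-style).
#' @param universe background gene universe (must contain all tested genes).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param namespaces optional named vector term -> namespace (BP/CC/MF);
#'   terms default to one namespace.
#' @return A `term_enrichment` data frame: subtype, term, namespace, overlap,
#'   p, padj, and a list-column `genes` of enriched genes.
#' @export
go_overrepresentation <- function(de_genes_by_subtype, gene_sets, universe,
                                  alpha = 0.05, namespaces = NULL) {
  namespaces <- namespaces %||% setNames(rep("BP", length(gene_sets)),
                                         names(gene_sets))
  N <- length(universe)
  rows <- list()
  for (k in names(de_genes_by_subtype)) {
    de <- intersect(de_genes_by_subtype[[k]], universe)
    if (!all(de_genes_by_subtype[[k]] %in% universe))
      stop("DE genes outside universe for subtype ", k, call. = FALSE)
    if (!length(de)) next
    for (j in names(gene_sets)) {
      term <- intersect(gene_sets[[j]], universe)
      if (!length(term)) {
        warning("term entirely outside universe, skipped: ", j)
        next
      }
      ov <- intersect(de, term)
      p <- stats::phyper(length(ov) - 1L, length(term), N - length(term),
                         length(de), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = k, term = j, namespace = unname(namespaces[j]),
        overlap = length(ov), p = p, stringsAsFactors = FALSE)
      rows[[length(rows)]]$genes <- I(list(ov))
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(subtype = character(0), term = character(0),
               namespace = character(0), overlap = integer(0),
               p = numeric(0))
  if (nrow(out)) {
    out$padj <- stats::ave(out$p, out$subtype, out$namespace,
                           FUN = function(p) p.adjust(p, "BH"))
    out <- out[out$padj <= alpha & out$overlap > 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("term_enrichment", class(out))
  out
}

#' Remove terms dominated by autopsy-associated genes
#'
#' A (subtype, term) enrichment is dropped iff strictly more than 20% of its
#' enriched genes belong to the autopsy-associated list — such terms reflect
#' postmortem artifacts rather than disease biology.
#'
#' @param terms a `term_enrichment` from [go_overrepresentation()].
#' @param autopsy_genes character vector (may be empty: identity).
#' @param max_frac maximal tolerated autopsy fraction (default 0.20).
#' @return the filtered `term_enrichment`.
#' @export
autopsy_filter <- function(terms, autopsy_genes, max_frac = 0.20) {
  if (!nrow(terms) || !length(autopsy_genes)) return(terms)
  frac <- vapply(terms$genes, function(g)
    if (length(g)) length(intersect(g, autopsy_genes)) / length(g) else 0,
    numeric(1))
  out <- terms[frac <= max_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster a subtype's enriched terms by gene overlap
#'
#' Within each subtype, terms are clustered by the Jaccard distance of their
#' enriched gene sets (agglomerative, cut at height `h`), so terms
#' identified from essentially the same genes share a cluster id.
#'
#' @param terms a `term_enrichment`.
#' @param h cut height (default 0.66).
#' @param method linkage (default `"complete"`, the [stats::hclust()] default).
#' @return `terms` with an added integer column `within_cluster`.
#' @export
cluster_terms_within_subtype <- function(terms, h = 0.66, method = "complete") {
  terms$within_cluster <- NA_integer_
  for (k in unique(terms$subtype)) {
    i <- which(terms$subtype == k)
    if (length(i) == 1L) { terms$within_cluster[i] <- 1L; next }
    sets <- terms$genes[i]
    names(sets) <- terms$term[i]
    d <- jaccard_dist_matrix(sets)
    hc <- stats::hclust(stats::as.dist(d), method = method)
    terms$within_cluster[i] <- stats::cutree(hc, h = h)
  }
  terms
}

#' Collapse terms across subtypes by co-clustering disagreement
#'
#' For every pair of terms, the distance is the fraction of subtypes — among
#' those where both terms are enriched — that assigned the two terms to
#' different within-subtype clusters; pairs never co-enriched get distance 1.
#' Average-linkage clustering of this distance, cut at `h`, merges terms
#' that the subtypes consistently identified from the same genes. Each
#' collapsed cluster is named after its member term with the least mean
#' log10 adjusted p across the subtypes where it is enriched.
#'
#' @param terms output of [cluster_terms_within_subtype()].
#' @param h cut height (default 0.66).
#' @return A `pathway_cluster`: list with `membership` (term -> cluster id),
#'   `representative` (cluster id -> term name), `distance` (f matrix).
#' @export
collapse_terms_across_subtypes <- function(terms, h = 0.66) {
  stopifnot("within_cluster" %in% names(terms))
  all_terms <- sort(unique(terms$term))
  n <- length(all_terms)
  f <- matrix(1, n, n, dimnames = list(all_terms, all_terms))
  diag(f) <- 0
  if (n >= 2L) {
    by_sub <- split(terms[, c("term", "within_cluster")], terms$subtype)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      agree <- vapply(by_sub, function(s) {
        ci <- s$within_cluster[s$term == all_terms[i]]
        cj <- s$within_cluster[s$term == all_terms[j]]
        if (!length(ci) || !length(cj)) return(NA)
        ci != cj
      }, logical(1))
      agree <- agree[!is.na(agree)]
      if (length(agree)) f[i, j] <- f[j, i] <- mean(agree)
    }
  }
  membership <- if (n == 1L) setNames(1L, all_terms) else
    stats::cutree(stats::hclust(stats::as.dist(f), method = "average"), h = h)
  mean_logp <- vapply(all_terms, function(tm)
    mean(log10(terms$padj[terms$term == tm])), numeric(1))
  representative <- vapply(split(all_terms, membership[all_terms]),
                           function(members) {
    members[which_extreme(mean_logp[members], members, max = FALSE)]
  }, character(1))
  structure(list(membership = membership, representative = representative,
                 distance = f), class = "pathway_cluster")
}

#' Min-log-p heatmap matrix and row groups
#'
#' Builds the (collapsed cluster x subtype) matrix of minimal -log10
#' adjusted p values (0 where a cluster has no enriched member term in a
#' subtype), trimmed at an upper bound of 10; rows are L1-normalized and
#' clustered with Ward linkage on L1 distance, cut at `h`; row groups of
#' size at least `min_group` are retained.
#'
#' @param clusters a `pathway_cluster`.
#' @param terms the `term_enrichment` the clusters came from.
#' @param h cut height (default 2.5).
#' @param min_group minimal group size retained (default 5).
#' @param cap upper bound on -log10 p (default 10).
#' @return list with `matrix` (raw, trimmed), `normalized`, `groups`
#'   (cluster id -> group), `retained` (group ids of size >= min_group).
#' @export
heatmap_groups <- function(clusters, terms, h = 2.5, min_group = 5L, cap = 10) {
  cl_of <- clusters$membership
  cids <- sort(unique(cl_of))
  subs <- sort(unique(terms$subtype))
  m <- matrix(0, length(cids), length(subs),
              dimnames = list(clusters$representative[as.character(cids)], subs))
  neglogp <- pmin(-log10(terms$padj), cap)
  for (r in seq_len(nrow(terms))) {
    ci <- match(cl_of[terms$term[r]], cids)
    sj <- match(terms$subtype[r], subs)
    m[ci, sj] <- max(m[ci, sj], neglogp[r])
  }
  rs <- rowSums(m)
  norm <- m / ifelse(rs == 0, 1, rs)
  if (nrow(m) >= 2L) {
    hc <- stats::hclust(stats::dist(norm, method = "manhattan"),
                        method = "ward.D")
    grp <- stats::cutree(hc, h = h)
  } else grp <- setNames(rep(1L, nrow(m)), rownames(m))
  sizes <- table(grp)
  list(matrix = m, normalized = norm, groups = setNames(grp, cids),
       retained = as.integer(names(sizes)[sizes >= min_group]))
}

#' 2D embedding of (subtype, pathway-cluster) pairs
#'
#' Each pair is characterized by the union of the enriched genes of the
#' cluster's terms within that subtype; pairwise Jaccard distances feed a
#' k-nearest-neighbor UMAP embedding (spread 1.5, min_dist 0.2) under a
#' fixed seed.
#'
#' @param terms a `term_enrichment`.
#' @param clusters a `pathway_cluster`.
#' @param k nearest neighbors (default 10; reduced with a warning when
#'   fewer pairs exist).
#' @param spread,min_dist UMAP layout parameters.
#' @param seed integer seed; same seed, same coordinates.
#' @return data frame: subtype, cluster, x, y.
#' @export
pair_embedding <- function(terms, clusters, k = 10L, spread = 1.5,
                           min_dist = 0.2, seed = 1L) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("pair_embedding requires uwot", call. = FALSE)
  key <- paste(terms$subtype, clusters$membership[terms$term], sep = "\r")
  sets <- lapply(split(terms$genes, key), function(g) unique(unlist(g)))
  n <- length(sets)
  if (n < k + 1L) {
    warning(sprintf("k reduced from %d to %d (only %d pairs)", k, n - 1L, n))
    k <- n - 1L
  }
  if (k < 2L) stop("too few pairs to embed", call. = FALSE)
  d <- jaccard_dist_matrix(sets)
  emb <- with_seed(substream_seed(seed, 41L),
    uwot::umap(stats::as.dist(d), n_neighbors = k, spread = spread,
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
               batch = TRUE))
  parts <- strsplit(names(sets), "\r", fixed = TRUE)
  data.frame(subtype = vapply(parts, `[`, character(1), 1L),
             cluster = as.integer(vapply(parts, `[`, character(1), 2L)),
             x = emb[, 1], y = emb[, 2], stringsAsFactors = FALSE)
}

#' Weighted-Jaccard similarity of subtypes over enriched pathways
#'
#' Each subtype is represented by its enriched pathways, down-weighting
#' pathways detected from similar genes within the subtype: the weight of
#' pathway i in subtype k is the inverse of the summed Jaccard similarities
#' of its enriched gene set to all of k's enriched pathways (including
#' itself, so weights are in (0, 1]). Subtype similarity is the weighted
#' Jaccard of the weight vectors (absent pathways weigh 0); hierarchical
#' clustering on 1 - similarity is cut at `h`.
#'
#' @param terms a `term_enrichment`.
#' @param h cut height (default 1.2).
#' @param method linkage (default `"average"`).
#' @return A `subtype_similarity`: list with `weights` (subtype x term),
#'   `similarity`, `assignment`.
#' @export
subtype_similarity <- function(terms, h = 1.2, method = "average") {
  subs <- sort(unique(terms$subtype))
  if (length(subs) < 2L) stop("need >= 2 subtypes with enriched terms", call. = FALSE)
  all_terms <- sort(unique(terms$term))
  W <- matrix(0, length(subs), length(all_terms),
              dimnames = list(subs, all_terms))
  for (k in subs) {
    rows <- which(terms$subtype == k)
    sets <- terms$genes[rows]
    for (a in seq_along(rows)) {
      ssum <- sum(vapply(sets, function(g) jaccard_sim(sets[[a]], g), numeric(1)))
      W[k, terms$term[rows[a]]] <- 1 / ssum
    }
  }
  sim <- matrix(1, length(subs), length(subs), dimnames = list(subs, subs))
  for (i in seq_along(subs)) for (j in seq_along(subs)) {
    if (i >= j) next
    sim[i, j] <- sim[j, i] <-
      sum(pmin(W[i, ], W[j, ])) / sum(pmax(W[i, ], W[j, ]))
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = method)
  structure(list(weights = W, similarity = sim,
                 assignment = stats::cutree(hc, h = h)),
            class = "subtype_similarity")
}
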