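#' Select genes for co-expression analysis within a cell cluster
#'
#' Removes genes expressed in fewer than `min_cells` cells of the cluster,
#' centers and scales the remainder, runs PCA, ranks genes by their highest
#' absolute loading on any component, and keeps the `top_n` highest-ranked
#' genes — the variation-carrying panel on which networks are built.
#'
#' @param data an [annotated_counts()].
#' @param cluster cluster name (at `level`; default the level-2 family).
#' @param level metadata column defining clusters.
#' @param min_cells minimum cells a gene must be detected in (default 20).
#' @param n_pcs number of components inspected (default 120).
#' @param top_n genes retained (default 5000).
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(data, cluster, level = "level2", min_cells = 20L,
                         n_pcs = 120L, top_n = 5000L) {
  stopifnot(inherits(data, "annotated_counts"))
  sel <- data$meta[[level]] == cluster
  if (sum(sel) < min_cells)
    stop(sprintf("cluster '%s' has %d cells (< %d)", cluster, sum(sel),
                 min_cells), call. = FALSE)
  x <- data$counts[sel, , drop = FALSE]
  keep <- Matrix::colSums(x > 0) >= min_cells
  x <- as.matrix(x[, keep, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  xs <- scale(x)
  rank_lim <- min(nrow(xs) - 1L, ncol(xs))
  n_pcs <- min(n_pcs, rank_lim)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  top_load <- apply(abs(p$rotation), 1, max)
  if (top_n > length(top_load)) {
    warning(sprintf("top_n (%d) exceeds available genes (%d); returning all",
                    top_n, length(top_load)))
    top_n <- length(top_load)
  }
  names(sort(top_load, decreasing = TRUE))[seq_len(top_n)]
}

# signed-hybrid adjacency: cor^beta where positive, 0 otherwise; zero diagonal
signed_hybrid_adjacency <- function(C, beta) {
  a <- ifelse(C > 0, C^beta, 0)
  diag(a) <- 0
  a
}

# scale-free topology fit: signed R^2 of log10 p(k) ~ log10 k over
# equal-width connectivity bins (positive when the slope is negative)
scale_free_fit <- function(k, n_breaks = 10L) {
  k <- k[k > 0]
  if (length(k) < n_breaks) return(NA_real_)
  cut_k <- cut(k, n_breaks)
  freq <- tapply(k, cut_k, length)
  km <- tapply(k, cut_k, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[ok] / sum(freq[ok])) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Pick the soft-thresholding power
#'
#' Scans powers 1..30: powers whose mean network connectivity lies at or
#' above the 95th percentile (too-dense networks) are discarded, and the
#' lowest surviving power reaching a scale-free topology fit R^2 of
#' `target_r2` is selected; if none does, the surviving power with the
#' highest R^2 is used.
#'
#' @param expr cells x genes expression matrix (>= 50 genes).
#' @param powers candidate powers (default 1:30).
#' @param target_r2 scale-free fit target (default 0.93).
#' @param conn_quantile connectivity discard quantile (default 0.95).
#' @return list with `power` and `table` (power, mean_connectivity, r2).
#' @export
pick_soft_threshold <- function(expr, powers = 1:30, target_r2 = 0.93,
                                conn_quantile = 0.95) {
  if (ncol(expr) < 50L) stop("need >= 50 genes", call. = FALSE)
  C <- stats::cor(as.matrix(expr))
  C[is.na(C)] <- 0
  tab <- data.frame(power = powers, mean_connectivity = NA_real_, r2 = NA_real_)
  for (i in seq_along(powers)) {
    a <- signed_hybrid_adjacency(C, powers[i])
    k <- rowSums(a)
    tab$mean_connectivity[i] <- mean(k)
    tab$r2[i] <- scale_free_fit(k)
  }
  cutoff <- quantile(tab$mean_connectivity, conn_quantile)
  surviving <- tab$mean_connectivity < cutoff
  cand <- tab[surviving & !is.na(tab$r2), , drop = FALSE]
  if (!nrow(cand)) cand <- tab[!is.na(tab$r2), , drop = FALSE]
  hit <- cand$power[cand$r2 >= target_r2]
  power <- if (length(hit)) min(hit) else
    cand$power[which.max(cand$r2)]
  list(power = power, table = tab)
}

# unsigned TOM from an adjacency with zero diagonal
tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Consensus topological overlap across cell resamples
#'
#' Draws `fraction` of the cells at random without replacement `n_resamples`
#' times; per resample computes the Pearson correlation, the signed-hybrid
#' adjacency cor^beta (positive correlations only) and the unsigned TOM,
#' then aggregates element-wise at the given quantile. Genes with zero
#' variance in any resample are dropped (the consensus good-gene filter).
#'
#' @param expr cells x genes expression matrix.
#' @param beta soft-thresholding power from [pick_soft_threshold()].
#' @param n_resamples number of resamples (default 20 at desk scale).
#' @param fraction cell fraction per resample (default 2/3).
#' @param quantile consensus quantile (default 0.5, the median).
#' @param seed integer seed.
#' @return A `tom_stack`: list with `tom` (consensus, genes x genes),
#'   `beta`, `removed` (bad genes), and the resample spec.
#' @export
consensus_tom <- function(expr, beta, n_resamples = 20L, fraction = 2 / 3,
                          quantile = 0.5, seed = 1L) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  n_draw <- floor(fraction * n)
  if (n_draw < 30L)
    stop(sprintf("resample size %d too small (< 30 cells)", n_draw),
         call. = FALSE)
  G <- ncol(expr)
  stack <- array(NA_real_, c(G, G, n_resamples))
  good <- rep(TRUE, G)
  with_seed(substream_seed(seed, 61L), {
    for (b in seq_len(n_resamples)) {
      ix <- sample.int(n, n_draw)
      sub <- expr[ix, , drop = FALSE]
      sds <- apply(sub, 2, stats::sd)
      good <- good & sds > 0
      C <- suppressWarnings(stats::cor(sub))
      C[is.na(C)] <- 0
      stack[, , b] <- tom_from_adjacency(signed_hybrid_adjacency(C, beta))
    }
  })
  cons <- apply(stack, c(1, 2), stats::quantile, probs = quantile)
  dimnames(cons) <- list(colnames(expr), colnames(expr))
  cons <- cons[good, good, drop = FALSE]
  structure(list(tom = cons, beta = beta, n_resamples = n_resamples,
                 fraction = fraction, quantile = quantile,
                 removed = colnames(expr)[!good]),
            class = "tom_stack")
}

#' Detect initial modules from a consensus TOM
#'
#' Average-linkage hierarchical clustering of 1 - TOM, cut with a
#' dynamic-hybrid-style procedure: a static cut (height scaled by the
#' `deep_split` sensitivity) yields core branches of at least `min_size`
#' genes; a PAM-like stage then assigns leftover genes to the module with
#' the highest mean TOM, provided they are at least as connected to it as
#' the module's weakest members. Remaining genes stay unassigned
#' (module 0, background).
#'
#' @param tom a `tom_stack` (or plain TOM matrix).
#' @param min_size minimum module size (default 15).
#' @param deep_split split sensitivity 0--4 (default 2).
#' @param pam_stage run the PAM-like assignment of leftovers (default TRUE).
#' @param cohesion required ratio of a module's mean within TOM to its
#'   mean TOM toward the remaining genes (default 30). Soft-threshold
#'   powering separates genuine co-expression from background by orders of
#'   magnitude; weakly inter-correlated blobs (sequencing-depth and
#'   compositional covariation) sit only one order above background and
#'   are rejected, both at core detection and again after the PAM growth
#'   stage.
#' @return named integer vector: module id per gene (0 = unassigned),
#'   labels ordered by decreasing module size; the dendrogram is attached
#'   as attribute `"hclust"`.
#' @export
detect_modules <- function(tom, min_size = 15L, deep_split = 2L,
                           pam_stage = TRUE, cohesion = 30) {
  m <- if (inherits(tom, "tom_stack")) tom$tom else tom
  genes <- colnames(m)
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  # average linkage is monotone; float noise at heights ~1 can still break
  # the ordering cutree requires
  hc$height <- cummax(hc$height)
  # cut relative to the height range (TOM distances can compress into a
  # narrow band near 1, so absolute heights are meaningless), scanning cut
  # levels and keeping the one that exposes the most cores — branches join
  # the background only near the top, so the scan adapts to branches of
  # different tightness; ties resolve to the tightest (lowest) cut, and
  # the PAM stage re-admits the periphery. A core must be cohesive: its
  # mean within TOM at least twice its mean TOM to the other genes, which
  # rejects the loose near-root clusters of mutually unconnected genes.
  max_frac <- c(0.9995, 0.999, 0.998, 0.995, 0.99)[deep_split + 1L]
  fracs <- seq(0.90, max_frac, length.out = 40L)
  h0 <- min(hc$height); hr <- diff(range(hc$height))
  G <- length(genes)
  core_ids <- function(labels) {
    sizes <- table(labels)
    cand <- as.integer(names(sizes)[sizes >= min_size &
                                      sizes <= ceiling(0.9 * G)])
    keep <- vapply(cand, function(cl) {
      member <- labels == cl
      n_m <- sum(member)
      within <- (sum(m[member, member]) - n_m) / (n_m * (n_m - 1L))
      between <- mean(m[member, !member])
      if (is.na(between)) return(TRUE)
      if (within < cohesion * between) return(FALSE)
      # the minimum size must be met by genuinely attached members, not
      # by background genes swept in near the root
      attach <- (rowSums(m[member, member, drop = FALSE]) - 1) / (n_m - 1L)
      sum(attach >= 2 * between) >= min_size
    }, logical(1))
    cand[keep]
  }
  cores_at <- lapply(fracs, function(f) {
    labels <- stats::cutree(hc, h = h0 + f * hr)
    list(labels = labels, cores = core_ids(labels))
  })
  n_cores <- vapply(cores_at, function(x) length(x$cores), integer(1))
  pick <- min(which(n_cores == max(n_cores)))
  labels <- cores_at[[pick]]$labels
  cores <- cores_at[[pick]]$cores
  assign <- integer(length(genes))
  names(assign) <- genes
  for (i in seq_along(cores)) assign[labels == cores[i]] <- i
  if (!length(cores)) {
    warning("no module reached min_size; all genes unassigned")
    return(structure(assign, hclust = hc))
  }
  if (pam_stage && any(assign == 0L)) {
    mods <- seq_along(cores)
    mean_tom <- vapply(mods, function(M) {
      member <- assign == M
      rowMeans(m[, member, drop = FALSE])
    }, numeric(length(genes)))
    # admission floor: geometric mean of the weakest core member's
    # within-module connectivity and the background level — powering
    # separates signal from background by orders of magnitude, so a gene
    # is admitted when its connectivity is nearer (log scale) to the
    # members' than to the background's
    bg_level <- vapply(mods, function(M) {
      out <- mean_tom[assign == 0L, M]
      max(stats::median(out), .Machine$double.xmin)
    }, numeric(1))
    floor_of <- vapply(mods, function(M) {
      member <- which(assign == M)
      weakest <- min(vapply(member, function(g)
        mean(m[g, setdiff(member, g)]), numeric(1)))
      sqrt(max(weakest, .Machine$double.xmin) * bg_level[M])
    }, numeric(1))
    for (g in which(assign == 0L)) {
      best <- which.max(mean_tom[g, ])
      if (mean_tom[g, best] >= floor_of[best]) assign[g] <- best
    }
  }
  # re-check cohesion on the grown modules: PAM growth must not have
  # diluted a core into a loose blob
  for (M in seq_along(cores)) {
    member <- assign == M
    n_m <- sum(member)
    if (n_m < 2L || n_m == G) next
    within <- (sum(m[member, member]) - n_m) / (n_m * (n_m - 1L))
    between <- mean(m[member, !member])
    if (within < cohesion * between) assign[member] <- 0L
  }
  assign <- relabel_by_size(assign)
  structure(assign, hclust = hc)
}

# renumber modules by decreasing size; ties break by the alphabetically
# first member gene, so labels are invariant to gene ordering
relabel_by_size <- function(assign) {
  ids <- sort(unique(assign[assign > 0L]))
  if (!length(ids)) return(assign)
  sz <- vapply(ids, function(i) sum(assign == i), integer(1))
  first <- vapply(ids, function(i) min(names(assign)[assign == i]),
                  character(1))
  ord <- ids[order(-sz, first)]
  remap <- setNames(seq_along(ord), ord)
  assign[assign > 0L] <- as.integer(remap[as.character(assign[assign > 0L])])
  assign
}

# kIM matrix: gene x module summed TOM to the module's members (self excluded)
kim_matrix <- function(assign, tom) {
  mods <- sort(unique(assign[assign > 0L]))
  K <- vapply(mods, function(M) {
    member <- assign == M
    s <- rowSums(tom[, member, drop = FALSE])
    s[member] <- s[member] - 1  # remove the unit self-TOM
    s
  }, numeric(length(assign)))
  dimnames(K) <- list(names(assign), paste0("M", mods))
  K
}

#' Refine modules: merge, reassign, prune
#'
#' Intramodular connectivity kIM(g, M) — the summed consensus TOM of gene g
#' to M's members — drives three refinement steps: (1) modules whose kIM
#' vectors correlate at `merge_cor` or higher are merged (transitively);
#' (2) iteratively, a gene is reassigned when its kIM to another module
#' exceeds `reassign_ratio` times the kIM to its current module, with kIM
#' recomputed between passes, until stable or `max_iter` passes;
#' (3) genes whose kIM is not significantly above the kIM of non-members to
#' that module (one-sided normal location test, BH-adjusted at `alpha`) are
#' pruned to background.
#'
#' @param assign initial assignment from [detect_modules()].
#' @param tom a `tom_stack` or TOM matrix.
#' @param merge_cor kIM-correlation merge threshold (default 0.85).
#' @param reassign_ratio reassignment ratio (default 1.25).
#' @param alpha BH-adjusted pruning level (default 0.05).
#' @param max_iter reassignment pass cap (default 50).
#' @return A `gene_modules`: list with `assignment`, `kim` (gene x module),
#'   `modules` (per module: genes, kim, weights summing to 1).
#' @export
refine_modules <- function(assign, tom, merge_cor = 0.85,
                           reassign_ratio = 1.25, alpha = 0.05,
                           max_iter = 50L) {
  m <- if (inherits(tom, "tom_stack")) tom$tom else tom
  assign <- assign[colnames(m)]
  if (!any(assign > 0L)) stop("no modules to refine", call. = FALSE)

  # (1) transitive merge of kIM-correlated modules
  repeat {
    K <- kim_matrix(assign, m)
    if (ncol(K) < 2L) break
    cc <- stats::cor(K)
    diag(cc) <- 0
    hit <- which(cc >= merge_cor, arr.ind = TRUE)
    if (!nrow(hit)) break
    i <- hit[1, 1]; j <- hit[1, 2]
    mods <- sort(unique(assign[assign > 0L]))
    assign[assign == mods[j]] <- mods[i]
    assign[assign > 0L] <- match(assign[assign > 0L],
                                 sort(unique(assign[assign > 0L])))
  }

  # (2) iterative kIM reassignment
  for (iter in seq_len(max_iter)) {
    K <- kim_matrix(assign, m)
    mods <- seq_len(ncol(K))
    moved <- 0L
    for (g in which(assign > 0L)) {
      cur <- assign[g]
      alt <- K[g, -cur]
      if (!length(alt)) next
      best <- which.max(alt)
      if (alt[best] > reassign_ratio * K[g, cur]) {
        assign[g] <- mods[-cur][best]
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
    if (iter == max_iter)
      warning("reassignment did not stabilize within max_iter; keeping last state")
  }

  # (3) prune genes whose kIM is not above the non-member background
  K <- kim_matrix(assign, m)
  p <- rep(NA_real_, length(assign))
  for (M in seq_len(ncol(K))) {
    member <- which(assign == M)
    bg <- K[assign != M, M]
    mu <- mean(bg); s <- stats::sd(bg)
    if (is.na(s) || s == 0) { p[member] <- 0; next }
    p[member] <- stats::pnorm(K[member, M], mu, s, lower.tail = FALSE)
  }
  tested <- !is.na(p)
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], "BH")
  assign[tested & padj > alpha] <- 0L
  # drop emptied modules, relabel by size
  keep <- sort(unique(assign[assign > 0L]))
  assign[assign > 0L] <- match(assign[assign > 0L], keep)
  if (!any(assign > 0L)) stop("pruning removed every module", call. = FALSE)
  assign <- relabel_by_size(assign)

  K <- kim_matrix(assign, m)
  modules <- lapply(seq_len(ncol(K)), function(M) {
    genes <- names(assign)[assign == M]
    kim <- K[genes, M]
    list(name = paste0("M", M), genes = genes, kim = kim,
         weights = kim / sum(kim))
  })
  names(modules) <- paste0("M", seq_along(modules))
  structure(list(assignment = assign, kim = K, modules = modules),
            class = "gene_modules")
}

#' Per-cell module expression
#'
#' Module expression is the weighted sum of per-gene standardized (z-scored)
#' expression, with kIM-derived weights scaled to sum to one.
#'
#' @param mods a `gene_modules`.
#' @param expr cells x genes expression matrix.
#' @return cells x modules matrix.
#' @export
module_expression <- function(mods, expr) {
  expr <- as.matrix(expr)
  out <- vapply(mods$modules, function(M) {
    x <- scale(expr[, M$genes, drop = FALSE])
    x[is.na(x)] <- 0
    as.numeric(x %*% M$weights)
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

# weighted Pearson correlation
weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

#' Module filter cascade
#'
#' Four ordered filters over refined modules: (i) overlap — a module is
#' removed when 75% or more of its genes also belong to a larger module
#' whose kIM vector it matches at a weighted Pearson correlation of 0.75 or
#' higher (weights emphasize the union's members, smoothed by kIM
#' magnitude); (ii) injury — the dot product of member kIMs with -log10
#' injury/postmortem DE p values is compared against a null from permuting
#' kIM gene labels, and significantly injury-loaded modules (p < 0.05) are
#' removed; (iii) sample confounding — per-cell module expression is fit
#' against each single-sample indicator and against condition, and modules
#' where any sample indicator explains more variance than condition are
#' removed; (iv) condition significance — only modules with a significant
#' condition coefficient (two-sided, `alpha`) survive, reported with CI.
#'
#' @param mods a `gene_modules` from [refine_modules()].
#' @param injury_p named per-gene p values from an injury/postmortem DE
#'   resource.
#' @param expr cells x genes expression matrix (same cells as `sample_ids`).
#' @param sample_ids,condition per-cell sample and condition labels.
#' @param overlap_frac,overlap_cor overlap-removal thresholds (0.75, 0.75).
#' @param n_perm injury-null permutations (default 1000).
#' @param alpha significance level for step (iv) (default 0.05).
#' @param seed integer seed for the injury permutations.
#' @return data frame per module: size, the four flags, injury_p,
#'   condition coefficient, CI, p, and `kept` (passed the whole cascade).
#' @export
filter_modules <- function(mods, injury_p, expr, sample_ids, condition,
                           overlap_frac = 0.75, overlap_cor = 0.75,
                           n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(mods, "gene_modules"))
  mnames <- names(mods$modules)
  sizes <- vapply(mods$modules, function(M) length(M$genes), integer(1))
  flags <- data.frame(module = mnames, size = sizes,
                      overlap_removed = FALSE, injury_removed = FALSE,
                      sample_confounded = FALSE, condition_significant = FALSE,
                      injury_perm_p = NA_real_, coef = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)

  # (i) overlap removal: smaller module goes
  K <- mods$kim
  active <- mnames
  for (a in mnames[order(sizes)]) {
    for (b in setdiff(active, a)) {
      if (sizes[b] <= sizes[a]) next
      ga <- mods$modules[[a]]$genes
      gb <- mods$modules[[b]]$genes
      if (length(intersect(ga, gb)) / length(ga) < overlap_frac) next
      w <- as.numeric(names(mods$assignment) %in% union(ga, gb))
      w <- w * (K[, a] + K[, b]) + 1e-8
      if (weighted_cor(K[, a], K[, b], w) >= overlap_cor) {
        flags$overlap_removed[flags$module == a] <- TRUE
        active <- setdiff(active, a)
        break
      }
    }
  }

  # (ii) injury permutation filter
  lp_all <- -log10(injury_p)
  for (a in intersect(active, mnames)) {
    M <- mods$modules[[a]]
    lp <- lp_all[M$genes]
    if (any(is.na(lp))) lp[is.na(lp)] <- 0
    obs <- sum(M$kim * lp)
    null <- with_seed(substream_seed(seed, 71L, match(a, mnames)), {
      vapply(seq_len(n_perm), function(b)
        sum(M$kim * sample(lp_all, length(M$genes))), numeric(1))
    })
    pp <- (1 + sum(null >= obs)) / (1 + n_perm)
    flags$injury_perm_p[flags$module == a] <- pp
    if (pp < 0.05) {
      flags$injury_removed[flags$module == a] <- TRUE
      active <- setdiff(active, a)
    }
  }

  # (iii) sample vs condition R^2; (iv) condition significance
  me <- module_expression(mods, expr)
  cond <- factor(condition, levels = c("control", "case"))
  for (a in intersect(active, mnames)) {
    y <- me[, a]
    r2_cond <- summary(stats::lm(y ~ cond))$r.squared
    r2_samp <- vapply(unique(sample_ids), function(s)
      summary(stats::lm(y ~ I(sample_ids == s)))$r.squared, numeric(1))
    if (max(r2_samp) > r2_cond) {
      flags$sample_confounded[flags$module == a] <- TRUE
      active <- setdiff(active, a)
      next
    }
    fit <- stats::lm(y ~ cond)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)["condcase", ]
    i <- flags$module == a
    flags$coef[i] <- sm["condcase", "Estimate"]
    flags$ci_lo[i] <- ci[1]; flags$ci_hi[i] <- ci[2]
    flags$p[i] <- sm["condcase", "Pr(>|t|)"]
    flags$condition_significant[i] <- flags$p[i] < alpha
  }
  flags$kept <- flags$module %in% active & flags$condition_significant
  flags
}

#' VIF-corrected rank-sum enrichment of a curated list in module kIMs
#'
#' Tests whether curated genes rank near the top of a module's gene
#' membership scores (kIM over all ranked genes) with a Wilcoxon rank-sum
#' statistic whose variance is inflated by VIF = 1 + (m - 1) * rho, where
#' rho is the mean pairwise expression correlation among the m curated
#' genes present (floored at 0) — correcting for the shared co-expression
#' that would otherwise overstate significance.
#'
#' @param kim named kIM vector of a module over all ranked genes.
#' @param curated_list curated gene ids.
#' @param expr cells x genes expression matrix (for the correlation).
#' @return list with `z`, `p` (one-sided, uncorrected), `vif`, `m`; caller
#'   applies Bonferroni across modules.
#' @export
vif_ranksum_enrichment <- function(kim, curated_list, expr) {
  genes <- names(kim)
  cur <- intersect(curated_list, genes)
  m <- length(cur)
  if (m < 2L)
    return(list(z = NA_real_, p = NA_real_, vif = NA_real_, m = m,
                flag = "fewer than 2 curated genes present"))
  cc <- suppressWarnings(stats::cor(as.matrix(expr[, cur, drop = FALSE])))
  rho <- max(0, mean(cc[upper.tri(cc)], na.rm = TRUE))
  vif <- 1 + (m - 1) * rho
  r <- rank(kim)
  n <- length(kim); n2 <- n - m
  U <- sum(r[cur]) - m * (m + 1) / 2
  mu <- m * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- m * n2 / 12 * ((n + 1) - tie_term)
  z <- (U - mu) / sqrt(vif * v)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE), vif = vif, m = m)
}
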