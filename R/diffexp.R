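#' Pseudobulk differential expression for one subtype
#'
#' Sums counts per (sample, gene) over the subtype's cells and tests
#' case vs control with a negative-binomial GLM per gene (DESeq2:
#' median-of-ratios size factors, trended dispersion shrinkage, Wald test).
#' Positive log2 fold changes mean higher expression in cases. All-zero
#' genes are excluded from the output.
#'
#' @param data an [annotated_counts()].
#' @param subtype subtype to test.
#' @param level metadata column holding the subtype annotation.
#' @param min_samples minimum samples per condition containing the subtype.
#' @return A `de_result`: list with `table` (gene, log2fc, Z, p, padj),
#'   `subtype`, `n_cells`, `samples`.
#' @export
pseudobulk_de <- function(data, subtype, level = "level4", min_samples = 2L) {
  stopifnot(inherits(data, "annotated_counts"))
  sel <- data$meta[[level]] == subtype
  if (!any(sel)) stop("subtype not present: ", subtype, call. = FALSE)
  pb <- pseudobulk_matrix(data, subtype, level)
  cond <- pb$condition
  if (sum(cond == "control") < min_samples || sum(cond == "case") < min_samples)
    stop(sprintf("insufficient replication for '%s': %d control, %d case samples",
                 subtype, sum(cond == "control"), sum(cond == "case")),
         call. = FALSE)
  if (!requireNamespace("DESeq2", quietly = TRUE))
    stop("pseudobulk_de requires DESeq2", call. = FALSE)
  mat <- pb$counts[rowSums(pb$counts) > 0, , drop = FALSE]
  col_data <- data.frame(condition = factor(cond, levels = c("control", "case")))
  dds <- suppressMessages(
    DESeq2::DESeqDataSetFromMatrix(mat, col_data, design = ~condition))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, name = "condition_case_vs_control")
  tab <- data.frame(gene = rownames(res), log2fc = res$log2FoldChange,
                    Z = res$stat, p = res$pvalue, padj = res$padj,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, subtype = subtype, n_cells = sum(sel),
                 samples = colnames(mat)), class = "de_result")
}

# genes x samples pseudobulk for one subtype (samples with >=1 cell)
pseudobulk_matrix <- function(data, subtype, level = "level4") {
  sel <- data$meta[[level]] == subtype
  counts <- data$counts[sel, , drop = FALSE]
  sample_id <- data$meta$sample_id[sel]
  agg <- rowsum(as.matrix(counts), sample_id)
  cond <- data$meta$condition[sel][match(rownames(agg), sample_id)]
  list(counts = t(agg), condition = setNames(cond, rownames(agg)))
}

#' Post-filter differentially expressed genes
#'
#' Keeps a gene iff its Wald statistic satisfies |Z| > `z_min` (strict) AND
#' its raw count exceeds `umi_min` in at least `cell_frac` of the subtype's
#' cells — restricting to genes with distinct expression rather than noise
#' at the detection limit.
#'
#' @param de a `de_result` from [pseudobulk_de()].
#' @param data the cohort the result came from.
#' @param z_min Wald-statistic threshold (default 3, strict).
#' @param umi_min count that must be exceeded (default 1 UMI, strict).
#' @param cell_frac minimum fraction of cells (default 0.05, inclusive).
#' @param level subtype annotation column.
#' @return character vector of retained gene ids.
#' @export
filter_de_genes <- function(de, data, z_min = 3, umi_min = 1,
                            cell_frac = 0.05, level = "level4") {
  stopifnot(inherits(de, "de_result"))
  hits <- de$table$gene[!is.na(de$table$Z) & abs(de$table$Z) > z_min]
  if (!length(hits)) return(character(0))
  expressed <- expressed_genes(data, subtypes = de$subtype, level = level,
                               umi_min = umi_min, cell_frac = cell_frac)
  intersect(hits, expressed)
}

#' Genes with distinct expression in given subtypes
#'
#' A gene is "expressed" in a subtype when its raw count exceeds `umi_min`
#' in at least `cell_frac` of that subtype's cells. The union over all
#' subtypes is the background universe for enrichment testing.
#'
#' @inheritParams filter_de_genes
#' @param subtypes subtypes to scan (default: all present).
#' @return character vector of gene ids (union across subtypes).
#' @export
expressed_genes <- function(data, subtypes = NULL, level = "level4",
                            umi_min = 1, cell_frac = 0.05) {
  stopifnot(inherits(data, "annotated_counts"))
  subtypes <- subtypes %||% unique(data$meta[[level]])
  out <- character(0)
  for (t in subtypes) {
    sel <- data$meta[[level]] == t
    if (!any(sel)) next
    frac <- Matrix::colSums(data$counts[sel, , drop = FALSE] > umi_min) / sum(sel)
    out <- union(out, colnames(data$counts)[frac >= cell_frac])
  }
  out
}

#' Fisher enrichment of DE genes in a curated gene list
#'
#' Tests over-representation of a gene list among the DE genes against the
#' expressed-gene background with Fisher's exact test. The odds-ratio
#' estimate h is the conditional maximum-likelihood estimate (maximizer of
#' the noncentral hypergeometric likelihood) with its exact 95% confidence
#' interval, as returned by [stats::fisher.test()].
#'
#' @param de_genes character vector of DE genes (subset of `background`).
#' @param gene_list curated list to test.
#' @param background expressed-gene universe.
#' @return An `enrichment_result`: list with `table` (2x2), `h`, `ci`, `p`.
#' @export
gene_list_enrichment <- function(de_genes, gene_list, background) {
  stopifnot(all(de_genes %in% background))
  lst <- intersect(gene_list, background)
  if (!length(lst)) {
    return(structure(list(table = NULL, h = NA_real_,
                          ci = c(NA_real_, NA_real_), p = NA_real_,
                          flag = "empty background intersection"),
                     class = "enrichment_result"))
  }
  a <- length(intersect(de_genes, lst))
  b <- length(de_genes) - a
  c_ <- length(lst) - a
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c("DE", "notDE"), c("inList", "notInList")))
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, h = unname(ft$estimate),
                 ci = unname(ft$conf.int), p = ft$p.value, flag = NULL),
            class = "enrichment_result")
}

#' Robust-regression residuals of a per-subtype count
#'
#' The number of DE genes grows linearly with the number of cells per
#' subtype (and the number of enriched GO terms with the number of DE
#' genes), so the raw counts are not comparable across subtypes. This fits
#' y = a*x + b by M-estimation with Huber loss (tuning constant 1.345,
#' iterated reweighting to convergence) and returns per-subtype residuals
#' y_observed - (a*x + b); subtypes above the line carry the signal.
#'
#' @param x predictor per subtype (e.g. cell counts); named.
#' @param y response per subtype (e.g. DE-gene counts), same order.
#' @return A `regression_residuals`: list with `slope`, `intercept`,
#'   `residuals` (named).
#' @export
residual_metric <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  ls <- stats::lm(y ~ x)
  if (max(abs(stats::residuals(ls))) < 1e-8 * max(1, max(abs(y)))) {
    # exact linear relation: the M-estimator's scale collapses, the LS fit
    # is already the robust fit
    fit <- ls
  } else {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                     maxit = 200, acc = 1e-8)
  }
  res <- y - (stats::coef(fit)[2] * x + stats::coef(fit)[1])
  names(res) <- names(x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = res),
            class = "regression_residuals")
}
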