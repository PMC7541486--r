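#' Ordinal classification of gene-list enrichment
#'
#' Based on the Fisher conditional-MLE odds ratio h: h > 1 marks a subtype
#' "affected" (1), a 95% CI lower bound above 1 "highly affected" (2), and
#' the largest h per class is the single "top-1" (3). Undefined h gets 0.
#'
#' @param results named list of `enrichment_result` objects (one per
#'   subtype) from [gene_list_enrichment()].
#' @param class_partition named vector subtype -> class.
#' @return data frame: subtype, class, h, ci_lower, category.
#' @export
categorize_enrichment <- function(results, class_partition) {
  subs <- names(results)
  h <- vapply(results, function(r) r$h %||% NA_real_, numeric(1))
  lo <- vapply(results, function(r) (r$ci %||% c(NA_real_, NA_real_))[1],
               numeric(1))
  cls <- class_partition[subs]
  cat <- integer(length(subs))
  cat[!is.na(h) & h > 1] <- 1L
  cat[!is.na(h) & h > 1 & !is.na(lo) & lo > 1] <- 2L
  cat <- assign_top1(cat, setNames(h, subs), cls, lower_is_worse = FALSE)
  data.frame(subtype = subs, class = unname(cls), h = unname(h),
             ci_lower = unname(lo), category = cat, stringsAsFactors = FALSE)
}

#' Ordinal classification of robust-regression residuals
#'
#' Subtypes above the regression line (positive residual) are "affected"
#' (1); among the affected, residuals strictly above their 75th percentile
#' (linear-interpolation convention) are "highly affected" (2); the largest
#' residual per class is the single "top-1" (3).
#'
#' @param res a `regression_residuals` from [residual_metric()].
#' @param class_partition named vector subtype -> class.
#' @return data frame: subtype, class, residual, category.
#' @export
categorize_count_residual <- function(res, class_partition) {
  r <- res$residuals
  cls <- class_partition[names(r)]
  cat <- integer(length(r))
  cat[r > 0] <- 1L
  aff <- r[r > 0]
  if (length(aff)) {
    thr <- unname(quantile(aff, 0.75, type = 7))
    cat[r > 0 & r > thr] <- 2L
  }
  cat <- assign_top1(cat, r, cls, lower_is_worse = FALSE)
  data.frame(subtype = names(r), class = unname(cls), residual = unname(r),
             category = cat, stringsAsFactors = FALSE)
}

#' Default impact-score metric weights
#'
#' A-priori trust weights: the expression-similarity score is the direct
#' measure (1.0); composition, GWAS enrichment, DE-gene count and GO-term
#' count carry 0.66; literature-curated epilepsy-gene enrichment, being
#' driven by prior knowledge, carries 0.33.
#'
#' @export
impact_weights <- function() c(similarity = 1.0, composition = 0.66,
                               go_count = 0.66, gwas = 0.66,
                               epilepsy = 0.33, de_count = 0.66)

#' Aggregate six per-subtype ordinal metrics into the impact score
#'
#' Each metric assigns every subtype a rank 0 (not affected) to 3 (the
#' class's single top-1 affected subtype); the impact total is the weighted
#' sum of ranks. Subtypes are ordered by total within class; ties break
#' deterministically by name.
#'
#' @param ranks subtype x metric matrix or data frame of integer ranks
#'   0--3; column names must match the weights.
#' @param class_partition named vector subtype -> class.
#' @param weights named metric weights (default [impact_weights()]).
#' @return An `impact_score` data frame: subtype, class, the six ranks,
#'   total, class_rank (1 = most affected in its class).
#' @export
aggregate_impact <- function(ranks, class_partition,
                             weights = impact_weights()) {
  ranks <- as.matrix(as.data.frame(ranks))
  miss <- setdiff(names(weights), colnames(ranks))
  if (length(miss))
    stop("missing metric rank(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ranks <- ranks[, names(weights), drop = FALSE]
  if (any(is.na(ranks)))
    stop("missing rank values for subtype(s): ",
         paste(rownames(ranks)[apply(is.na(ranks), 1, any)], collapse = ", "),
         call. = FALSE)
  if (!all(ranks %in% 0:3)) stop("ranks must be integers 0..3", call. = FALSE)
  total <- as.numeric(ranks %*% weights)
  cls <- class_partition[rownames(ranks)]
  ord <- order(cls, -total, rownames(ranks))
  class_rank <- integer(length(total))
  class_rank[ord] <- stats::ave(seq_along(ord), cls[ord], FUN = seq_along)
  out <- data.frame(subtype = rownames(ranks), class = unname(cls),
                    as.data.frame(ranks), total = total,
                    class_rank = class_rank, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("impact_score", class(out))
  out
}
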