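#' Joint PCA of a normalized cell x gene matrix
#'
#' Fits PCA on the row-bound normalized matrix of all cells (both
#' conditions jointly), gene-centered, and returns per-cell component
#' scores. Component signs are fixed by convention: the largest-magnitude
#' gene loading of each component is made positive, so results are
#' deterministic.
#'
#' @param norm result of [total_count_normalize()] or a cells x genes matrix.
#' @param n_components number of principal components (default 100; reduced
#'   with a warning when the matrix has lower rank).
#' @param scale. scale genes to unit variance before rotation (default FALSE).
#' @return list with `scores` (cells x components), `rotation`, `sdev`,
#'   `center`.
#' @export
joint_pca <- function(norm, n_components = 100L, scale. = FALSE) {
  x <- if (is.list(norm) && !is.null(norm$matrix)) norm$matrix else norm
  x <- as.matrix(x)
  if (all(apply(x, 2, stats::var) == 0))
    stop("degenerate input: all genes have zero variance", call. = FALSE)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warning(sprintf("n_components reduced from %d to %d (matrix rank limit)",
                    n_components, max_rank))
    n_components <- max_rank
  }
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = n_components)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, rotation = p$rotation, sdev = p$sdev[seq_len(n_components)],
       center = p$center)
}

#' Per-(subtype, sample) centroids in PC space
#'
#' The centroid of a subtype in one sample is the arithmetic mean of its
#' cells' PC scores. Groups with fewer than `min_cells` cells are omitted
#' (recorded in the `omitted` attribute).
#'
#' @param scores cells x components matrix from [joint_pca()].
#' @param meta cell metadata aligned with `scores` rows.
#' @param min_cells minimum cells per (subtype, sample) group (default 5).
#' @param level metadata column with the subtype annotation.
#' @return A `centroid_set`: list with `centroids` (named list, per subtype a
#'   samples x components matrix) and `sample_condition` (named vector).
#' @export
subtype_sample_centroids <- function(scores, meta, min_cells = 5L,
                                     level = "level4") {
  stopifnot(nrow(scores) == nrow(meta))
  key <- interaction(meta[[level]], meta$sample_id, drop = TRUE, sep = "\r")
  sizes <- table(key)
  cents <- rowsum(scores, key) / as.vector(sizes[levels(droplevels(key))])
  parts <- strsplit(rownames(cents), "\r", fixed = TRUE)
  subtype <- vapply(parts, `[`, character(1), 1L)
  sample_id <- vapply(parts, `[`, character(1), 2L)
  ok <- as.vector(sizes) >= min_cells
  omitted <- paste(subtype[!ok], sample_id[!ok], sep = "/")
  out <- list(
    centroids = lapply(split(seq_along(subtype)[ok], subtype[ok]), function(i) {
      m <- cents[i, , drop = FALSE]
      rownames(m) <- sample_id[i]
      m
    }),
    sample_condition = setNames(meta$condition[!duplicated(meta$sample_id)],
                                meta$sample_id[!duplicated(meta$sample_id)])
  )
  attr(out, "omitted") <- omitted
  class(out) <- "centroid_set"
  out
}

#' Expression-similarity scores across conditions
#'
#' For each subtype, all pairwise Pearson correlations between its sample
#' centroids are computed over the PC coordinates. The control baseline is
#' the 40% trimmed mean of control--control correlations; the control
#' deviation is their MAD. Every (control, case) correlation is then
#' standardized against that baseline: z = (c - m) / sigma. Scores around 0
#' mean the condition left the subtype's transcriptional profile unchanged;
#' negative scores mean divergence.
#'
#' @param centroids a `centroid_set` from [subtype_sample_centroids()].
#' @param trim per-tail trim fraction of the baseline mean (default 0.4).
#' @param mad_constant MAD scale constant (default 1.4826).
#' @param min_control minimum control samples with a centroid (default 3).
#' @return A `similarity_result`: list with `summary` (per-subtype data
#'   frame: n_pairs, m, sigma, z quartiles, degenerate flag) and `pairs`
#'   (long table of all scored pairs).
#' @export
similarity_scores <- function(centroids, trim = 0.4, mad_constant = 1.4826,
                              min_control = 3L) {
  stopifnot(inherits(centroids, "centroid_set"))
  cond <- centroids$sample_condition
  sum_rows <- list(); pair_rows <- list()
  for (t in names(centroids$centroids)) {
    cent <- centroids$centroids[[t]]
    ctl <- rownames(cent)[cond[rownames(cent)] == "control"]
    cas <- rownames(cent)[cond[rownames(cent)] == "case"]
    if (length(ctl) < min_control || length(cas) < 1L) next
    # Pearson over PC coordinates; constant centroids give NA, handled below
    cc <- suppressWarnings(stats::cor(t(cent)))
    ctl_pairs <- utils::combn(ctl, 2L)
    c_ctl <- cc[cbind(ctl_pairs[1, ], ctl_pairs[2, ])]
    m_t <- trimmed_mean(c_ctl, trim)
    s_t <- mad_dev(c_ctl, mad_constant)
    # zero MAD (identical control profiles) or undefined correlations
    # (constant centroids) leave no usable baseline
    degenerate <- is.na(m_t) || is.na(s_t) || s_t == 0
    grid <- expand.grid(control = ctl, case = cas, stringsAsFactors = FALSE)
    c_cc <- cc[cbind(grid$control, grid$case)]
    z <- if (degenerate) rep(NA_real_, nrow(grid)) else (c_cc - m_t) / s_t
    pair_rows[[t]] <- data.frame(subtype = t, control = grid$control,
                                 case = grid$case, c = c_cc, z = z,
                                 stringsAsFactors = FALSE)
    q <- if (degenerate) rep(NA_real_, 3L) else
      unname(quantile(z, c(0.25, 0.5, 0.75)))
    sum_rows[[t]] <- data.frame(
      subtype = t, n_pairs = nrow(grid), m = m_t, sigma = s_t,
      z_q25 = q[1], z_median = q[2], z_q75 = q[3],
      degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, sum_rows) %||%
                data.frame(subtype = character(0)),
              pairs = do.call(rbind, pair_rows))
  rownames(out$summary) <- NULL
  class(out) <- "similarity_result"
  out
}

# shared ordinal machinery: given per-subtype values where LOWER (or higher)
# means more affected, the top-1 per class is forced to rank 3
assign_top1 <- function(category, value, cls, lower_is_worse = TRUE) {
  for (k in unique(cls)) {
    i <- which(cls == k & !is.na(value))
    if (!length(i)) next
    top <- i[which_extreme(value[i], names(value)[i] %||% as.character(i),
                           max = !lower_is_worse)]
    category[top] <- 3L
  }
  category
}

#' Ordinal classification of similarity scores
#'
#' A subtype is "affected" (1) when the upper quartile of its z scores is
#' below zero; "highly affected" (2) when additionally its median is below
#' the median of all subtype medians in its class; the subtype with the
#' lowest median per class is the single "top-1" (3). Degenerate-baseline
#' subtypes get NA.
#'
#' @param result a `similarity_result`.
#' @param class_partition named character vector mapping subtype to class
#'   (principal / interneuron).
#' @return data frame with subtype, class, category (0--3).
#' @export
classify_similarity <- function(result, class_partition) {
  s <- result$summary[!result$summary$degenerate &
                        !is.na(result$summary$z_median), , drop = FALSE]
  if (!nrow(s)) stop("no subtype with a usable similarity score", call. = FALSE)
  cls <- class_partition[s$subtype]
  cat <- integer(nrow(s))
  cat[s$z_q75 < 0] <- 1L
  for (k in unique(cls)) {
    i <- cls == k
    mom <- median(s$z_median[i])
    cat[i & cat >= 1L & s$z_median < mom] <- 2L
  }
  med <- setNames(s$z_median, s$subtype)
  cat <- assign_top1(cat, med, cls, lower_is_worse = TRUE)
  data.frame(subtype = s$subtype, class = unname(cls), category = cat,
             stringsAsFactors = FALSE)
}
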