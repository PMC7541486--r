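#' Annotated cell x gene count container
#'
#' A sparse integer count matrix (cells in rows) with per-cell metadata:
#' sample of origin, condition (control/case), the four-level subtype
#' annotation and the principal/interneuron class. The condition must be
#' constant within a sample, cell ids unique, and gene ids unique.
#'
#' @param counts cells x genes matrix (coerced to sparse); non-negative.
#' @param meta data frame with columns cell_id, sample_id, condition,
#'   level1..level4, class; one row per matrix row.
#' @return An `annotated_counts` object.
#' @export
annotated_counts <- function(counts, meta) {
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  meta <- as.data.frame(meta)
  need <- c("cell_id", "sample_id", "condition", "level1", "level2",
            "level3", "level4", "class")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != nrow(counts))
    stop(sprintf("dimension mismatch: %d cells in matrix, %d metadata rows",
                 nrow(counts), nrow(meta)), call. = FALSE)
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene ids", call. = FALSE)
  if (!all(meta$condition %in% c("control", "case")))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(meta$condition), c("control", "case")),
               collapse = ", "), call. = FALSE)
  bad <- tapply(meta$condition, meta$sample_id,
                function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop("condition not constant within sample(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  rownames(counts) <- meta$cell_id
  rownames(meta) <- meta$cell_id
  structure(list(counts = counts, meta = meta), class = "annotated_counts")
}

#' @method print annotated_counts
#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d cells x %d genes; %d samples (%d control, %d case); %d subtypes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$sample_id)),
              length(unique(x$meta$sample_id[x$meta$condition == "control"])),
              length(unique(x$meta$sample_id[x$meta$condition == "case"])),
              length(unique(x$meta$level4))))
  invisible(x)
}

#' @method dim annotated_counts
#' @export
dim.annotated_counts <- function(x) dim(x$counts)

subset_cells <- function(data, keep) {
  annotated_counts(data$counts[keep, , drop = FALSE],
                   data$meta[keep, , drop = FALSE])
}

#' Write / load an annotated cohort (MatrixMarket + TSV)
#'
#' The on-disk layout is a sparse `matrix.mtx` (cells in rows), a
#' `genes.tsv` (one id per line) and a `metadata.tsv` with the cell
#' annotation columns.
#'
#' @param data an [annotated_counts()] object.
#' @param dir output directory (created if needed).
#' @return `write_counts` returns `dir` invisibly; `load_counts` returns the
#'   validated [annotated_counts()].
#' @export
write_counts <- function(data, dir) {
  stopifnot(inherits(data, "annotated_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(data$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(data$counts), file.path(dir, "genes.tsv"))
  cols <- c("cell_id", "sample_id", "condition", "level1", "level2",
            "level3", "level4", "class")
  utils::write.table(data$meta[, cols], file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @param mtx_path,genes_path,metadata_path file paths (cells in matrix rows).
#' @rdname write_counts
#' @export
load_counts <- function(mtx_path, genes_path, metadata_path) {
  for (p in c(mtx_path, genes_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (length(genes) != ncol(counts))
    stop(sprintf("dimension mismatch: %d genes listed, %d matrix columns",
                 length(genes), ncol(counts)), call. = FALSE)
  if (nrow(meta) != nrow(counts))
    stop(sprintf("dimension mismatch: %d metadata rows, %d matrix rows",
                 nrow(meta), nrow(counts)), call. = FALSE)
  colnames(counts) <- genes
  annotated_counts(counts, meta)
}

#' Quality-control cell filtering
#'
#' Droplet profile: removes cells whose mitochondrial count fraction exceeds
#' 8%. Plate profile: removes cells with fewer than 2000 detected genes,
#' more than one million total reads, or mitochondrial fraction above 5%,
#' then drops genes present in fewer than five cells. Mitochondrial genes
#' are named explicitly by id (synthetic genes carry no MT- prefix); use
#' [mito_genes_by_prefix()] for conventionally named data.
#'
#' @param data an [annotated_counts()].
#' @param profile `"droplet"` or `"plate"`.
#' @param mito_gene_ids character vector of mitochondrial gene ids (may be
#'   empty).
#' @param mito_max,min_genes,max_reads,min_cells_per_gene thresholds;
#'   defaults follow the profile.
#' @return filtered [annotated_counts()]; the retained-cell mask is attached
#'   as attribute `"kept_cells"` for audit.
#' @export
qc_filter_cells <- function(data, profile = c("droplet", "plate"),
                            mito_gene_ids = character(0),
                            mito_max = NULL, min_genes = 2000L,
                            max_reads = 1e6, min_cells_per_gene = 5L) {
  profile <- match.arg(profile)
  stopifnot(inherits(data, "annotated_counts"))
  counts <- data$counts
  total <- Matrix::rowSums(counts)
  mito_idx <- intersect(mito_gene_ids, colnames(counts))
  mito_frac <- if (length(mito_idx))
    Matrix::rowSums(counts[, mito_idx, drop = FALSE]) / pmax(total, 1)
  else rep(0, nrow(counts))
  if (profile == "droplet") {
    mito_max <- mito_max %||% 0.08
    keep <- mito_frac <= mito_max
  } else {
    mito_max <- mito_max %||% 0.05
    n_genes <- Matrix::rowSums(counts > 0)
    keep <- n_genes >= min_genes & total <= max_reads & mito_frac <= mito_max
  }
  if (!any(keep))
    stop("QC removed every cell; review thresholds", call. = FALSE)
  out <- subset_cells(data, keep)
  if (profile == "plate") {
    gene_keep <- Matrix::colSums(out$counts > 0) >= min_cells_per_gene
    out$counts <- out$counts[, gene_keep, drop = FALSE]
  }
  attr(out, "kept_cells") <- keep
  out
}

#' @param ids gene ids; @param prefix regular expression for mitochondrial ids.
#' @rdname qc_filter_cells
#' @export
mito_genes_by_prefix <- function(ids, prefix = "^MT-") grep(prefix, ids, value = TRUE)

#' Drop samples with too many sparse subtypes
#'
#' A sample is removed when the number of subtypes with fewer than
#' `min_cells` cells strictly exceeds `max_sparse_subtypes` — samples
#' missing many subtypes bias downstream per-subtype analyses.
#'
#' @param data an [annotated_counts()].
#' @param min_cells a subtype with fewer cells than this counts as sparse.
#' @param max_sparse_subtypes tolerated number of sparse subtypes.
#' @param level metadata column holding the subtype annotation.
#' @return character vector of retained sample ids.
#' @export
filter_samples_by_coverage <- function(data, min_cells = 5L,
                                       max_sparse_subtypes = 5L,
                                       level = "level4") {
  stopifnot(inherits(data, "annotated_counts"))
  subtypes <- sort(unique(data$meta[[level]]))
  samples <- unique(data$meta$sample_id)
  tab <- table(factor(data$meta$sample_id, samples),
               factor(data$meta[[level]], subtypes))
  n_sparse <- rowSums(tab < min_cells)
  samples[n_sparse <= max_sparse_subtypes]
}

#' Total-count normalization
#'
#' Scales every cell to a constant total of `scale` counts, optionally
#' followed by log(1 + x). Cells in rows throughout.
#'
#' @param data an [annotated_counts()] or a cells x genes matrix.
#' @param scale target row total (default 1e4).
#' @param log1p apply log(1+x) after scaling.
#' @return list with `matrix` (sparse, cells x genes), `scale`, `log1p`.
#' @export
total_count_normalize <- function(data, scale = 1e4, log1p = FALSE) {
  counts <- if (inherits(data, "annotated_counts")) data$counts else
    methods::as(as(data, "CsparseMatrix"), "generalMatrix")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("all-zero cell(s): ",
         paste(utils::head(rownames(counts)[totals == 0], 5L), collapse = ", "),
         call. = FALSE)
  m <- Matrix::Diagonal(x = scale / totals) %*% counts
  dimnames(m) <- dimnames(counts)
  if (log1p) m@x <- log1p(m@x)
  list(matrix = m, scale = scale, log1p = log1p)
}

#' Filter a cell-type label-match table
#'
#' For counts n[i, j] of cells of local type i labeled as external type j,
#' a match is retained iff n[i, j] >= `min_count` and n[i, j] / sum_k n[i, k]
#' >= `min_fraction` (singletons and sub-5% matches are treated as mapping
#' noise).
#'
#' @param match non-negative integer matrix, local types in rows.
#' @param min_count minimum absolute match count (default 2: singletons drop).
#' @param min_fraction minimum within-row fraction (default 0.05).
#' @return list with `counts` (entries failing the rules zeroed) and
#'   `retained` (logical matrix).
#' @export
filter_label_matches <- function(match, min_count = 2L, min_fraction = 0.05) {
  match <- as.matrix(match)
  if (any(match < 0)) stop("negative match counts", call. = FALSE)
  rs <- rowSums(match)
  zero_rows <- rs == 0
  if (any(zero_rows))
    warning("zero-count local type(s) skipped: ",
            paste(rownames(match)[zero_rows], collapse = ", "))
  frac <- match / ifelse(rs == 0, 1, rs)
  retained <- match >= min_count & frac >= min_fraction
  out <- match
  out[!retained] <- 0L
  list(counts = out, retained = retained)
}

#' Gene-set and gene-list file formats
#'
#' GMT files are tab-separated: set name, description, then member genes.
#' Gene-list files hold one symbol per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (defaults to the names).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
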