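# toy annotated cohort built by hand: counts is cells x genes, one row of
# metadata per cell derived from compact per-cell labels
toy_counts <- function(counts, sample_id, condition = NULL, subtype = "S1",
                       class = "principal") {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  sample_id <- rep(sample_id, length.out = n)
  condition <- condition %||%
    ifelse(grepl("^C", sample_id), "control", "case")
  subtype <- rep(subtype, length.out = n)
  class <- rep(class, length.out = n)
  meta <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    sample_id = sample_id, condition = rep(condition, length.out = n),
    level1 = ifelse(class == "principal", "Excitatory", "Inhibitory"),
    level2 = subtype, level3 = subtype, level4 = subtype, class = class,
    stringsAsFactors = FALSE)
  annotated_counts(counts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default cohorts reused across tests
null_cohort <- function(seed = 1L, n_subtypes = 4L, n_genes = 80L,
                        cells = 12L, n_control = 4L, n_case = 4L) {
  generate_cohort(cohort_config(
    n_control_samples = n_control, n_case_samples = n_case,
    n_subtypes = n_subtypes, n_genes = n_genes,
    cells_per_subtype = cells, seed = seed))
}

effect_cohort <- function(seed = 1L, subtype = "L2_Cux2_a", n_de = 40L,
                          log2fc = 2, n_genes = 200L, cells = 20L,
                          n_subtypes = 8L, ...) {
  generate_cohort(cohort_config(
    n_subtypes = n_subtypes, n_genes = n_genes, cells_per_subtype = cells,
    affected_subtypes = data.frame(subtype = subtype, n_de_genes = n_de,
                                   log2fc = log2fc),
    seed = seed, ...))
}

# planted-membership vector (0 = background) from a truth record
module_truth_labels <- function(truth) {
  lab <- setNames(rep(0L, length(truth$genes)), truth$genes)
  for (i in seq_along(truth$modules)) lab[truth$modules[[i]]$genes] <- i
  lab
}
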