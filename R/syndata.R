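#' Configuration for a synthetic case/control snRNA-seq cohort
#'
#' Describes the cohort the generator emulates: roughly ten control and nine
#' case donors, 20--40 neuronal subtypes in a four-level hierarchy split into
#' principal and interneuron classes, negative-binomial counts with
#' per-subtype expression programs, and optional planted condition effects
#' (differential expression, latent-factor co-expression modules, and
#' composition shifts) with known ground truth.
#'
#' @param n_control_samples,n_case_samples number of donors per condition.
#' @param n_subtypes number of level-4 subtypes (split across a fixed
#'   principal/interneuron family template).
#' @param cells_per_subtype expected cells per (sample, subtype); realized
#'   counts are Poisson around this mean.
#' @param n_genes number of genes.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); scalar shared across genes, or one value per
#'   gene.
#' @param library_size list with `meanlog` and `sdlog` of the log-normal
#'   per-cell library size.
#' @param program_frac,program_sdlog fraction of genes given a subtype-specific
#'   log-normal expression multiplier, and its log-sd; these markers are what
#'   separates subtypes in PCA space.
#' @param affected_subtypes data frame with columns `subtype`, `n_de_genes`,
#'   `log2fc` naming subtypes given a planted condition effect (half the
#'   chosen genes up, half down, at the stated magnitude).
#' @param planted_modules list of module specs, each a list with `size`
#'   (genes), `loading` (log-sd of the per-cell latent factor), `subtypes`
#'   (character scope, NULL = all cells) and `coupling` (shift of the factor's
#'   log-mean in case cells; 0 = condition-independent).
#' @param composition_shifts data frame with columns `subtype`, `ratio`:
#'   expected case cell counts for that subtype are multiplied by `ratio`.
#' @param seed integer seed; all generator randomness derives from it through
#'   independent substreams, so the same config and seed regenerate the cohort
#'   bit-identically.
#' @return A validated `cohort_config` object (a list).
#' @export
cohort_config <- function(n_control_samples = 10L, n_case_samples = 9L,
                          n_subtypes = 24L, cells_per_subtype = 30,
                          n_genes = 500L, nb_dispersion = 0.4,
                          library_size = list(meanlog = log(2000), sdlog = 0.3),
                          program_frac = 0.1, program_sdlog = 0.8,
                          affected_subtypes = NULL, planted_modules = list(),
                          composition_shifts = NULL, seed = 1L) {
  if (n_control_samples < 1L) stop_config("n_control_samples", "must be >= 1")
  if (n_case_samples < 1L) stop_config("n_case_samples", "must be >= 1")
  if (n_subtypes < 2L) stop_config("n_subtypes", "must be >= 2")
  if (n_genes < 10L) stop_config("n_genes", "must be >= 10")
  if (any(nb_dispersion <= 0)) stop_config("nb_dispersion", "must be positive")
  if (!length(nb_dispersion) %in% c(1L, n_genes))
    stop_config("nb_dispersion", "length must be 1 or n_genes")
  if (cells_per_subtype <= 0) stop_config("cells_per_subtype", "must be positive")
  if (!is.list(library_size) || is.null(library_size$meanlog) ||
      is.null(library_size$sdlog))
    stop_config("library_size", "needs meanlog and sdlog")

  subtypes <- subtype_hierarchy(n_subtypes)
  if (!is.null(affected_subtypes)) {
    affected_subtypes <- as.data.frame(affected_subtypes)
    need <- c("subtype", "n_de_genes", "log2fc")
    if (!all(need %in% names(affected_subtypes)))
      stop_config("affected_subtypes", "needs columns subtype, n_de_genes, log2fc")
    bad <- setdiff(affected_subtypes$subtype, subtypes$level4)
    if (length(bad))
      stop_config("affected_subtypes",
                  paste("unknown subtype(s):", paste(bad, collapse = ", ")))
  }
  if (!is.null(composition_shifts)) {
    composition_shifts <- as.data.frame(composition_shifts)
    if (!all(c("subtype", "ratio") %in% names(composition_shifts)))
      stop_config("composition_shifts", "needs columns subtype, ratio")
    bad <- setdiff(composition_shifts$subtype, subtypes$level4)
    if (length(bad))
      stop_config("composition_shifts",
                  paste("unknown subtype(s):", paste(bad, collapse = ", ")))
    if (any(composition_shifts$ratio <= 0))
      stop_config("composition_shifts", "ratios must be positive")
  }
  for (m in planted_modules) {
    if (is.null(m$size) || m$size < 2L || m$size > n_genes)
      stop_config("planted_modules", "each module needs 2 <= size <= n_genes")
    if (is.null(m$loading) || m$loading <= 0)
      stop_config("planted_modules", "each module needs loading > 0")
    if (!is.null(m$subtypes)) {
      bad <- setdiff(m$subtypes, subtypes$level4)
      if (length(bad))
        stop_config("planted_modules",
                    paste("unknown subtype(s):", paste(bad, collapse = ", ")))
    }
  }

  structure(list(
    n_control_samples = as.integer(n_control_samples),
    n_case_samples = as.integer(n_case_samples),
    n_subtypes = as.integer(n_subtypes),
    cells_per_subtype = cells_per_subtype,
    n_genes = as.integer(n_genes),
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    program_frac = program_frac, program_sdlog = program_sdlog,
    affected_subtypes = affected_subtypes,
    planted_modules = planted_modules,
    composition_shifts = composition_shifts,
    subtypes = subtypes,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# fixed four-level hierarchy template; names echo cortical-neuron
# nomenclature purely for readable reports
subtype_hierarchy <- function(n_subtypes) {
  fam <- data.frame(
    level2 = c("L2_Cux2", "L4_Rorb", "L5_6_Themis", "L5_6_Fezf2",
               "Pvalb", "Sst", "Vip", "Id3"),
    level1 = rep(c("Excitatory", "Inhibitory"), each = 4L),
    class = rep(c("principal", "interneuron"), each = 4L),
    stringsAsFactors = FALSE
  )
  idx <- rep(seq_len(nrow(fam)), length.out = n_subtypes)
  idx <- sort(idx)
  out <- fam[idx, , drop = FALSE]
  within_fam <- stats::ave(seq_len(n_subtypes), out$level2, FUN = seq_along)
  out$level3 <- paste0(out$level2, "_grp", (within_fam + 1L) %/% 2L)
  out$level4 <- paste0(out$level2, "_", letters[within_fam])
  rownames(out) <- NULL
  out[, c("class", "level1", "level2", "level3", "level4")]
}

#' Generate a synthetic annotated cohort with planted ground truth
#'
#' Draws counts per cell as NB(mean = library-size share x subtype program x
#' condition effect x module factor, dispersion) via a gamma--Poisson
#' mixture. Cell metadata carries sample, condition and the four-level
#' subtype labels plus the principal/interneuron class. The returned truth
#' record (planted DE genes, module memberships, composition ratios) is a
#' pure function of the config and seed.
#'
#' @param config a [cohort_config()].
#' @return list with `data` (an [annotated_counts()] object) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  G <- config$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  subtypes <- config$subtypes
  S <- nrow(subtypes)
  samples <- data.frame(
    sample_id = c(sprintf("CNT%d", seq_len(config$n_control_samples)),
                  sprintf("EP%d", seq_len(config$n_case_samples))),
    condition = rep(c("control", "case"),
                    c(config$n_control_samples, config$n_case_samples)),
    stringsAsFactors = FALSE
  )

  gene_base <- with_seed(substream_seed(config$seed, 1L),
                         stats::rlnorm(G, meanlog = 1, sdlog = 1))

  # subtype expression programs: log-normal multipliers on a random marker set
  program <- with_seed(substream_seed(config$seed, 2L), {
    P <- matrix(1, S, G, dimnames = list(subtypes$level4, genes))
    n_mark <- max(1L, round(config$program_frac * G))
    for (t in seq_len(S)) {
      mk <- sample.int(G, n_mark)
      P[t, mk] <- stats::rlnorm(n_mark, 0, config$program_sdlog)
    }
    P
  })

  # planted DE truth: per affected subtype, signed log2 fold changes
  truth_de <- NULL
  cond_mult <- matrix(1, S, G, dimnames = list(subtypes$level4, genes))
  aff <- config$affected_subtypes
  if (!is.null(aff) && nrow(aff)) {
    truth_de <- with_seed(substream_seed(config$seed, 3L), {
      recs <- lapply(seq_len(nrow(aff)), function(i) {
        n_de <- aff$n_de_genes[i]
        gidx <- sample.int(G, n_de)
        sgn <- rep(c(1, -1), length.out = n_de)
        data.frame(subtype = aff$subtype[i], gene = genes[gidx],
                   log2fc = sgn * abs(aff$log2fc[i]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, recs)
    })
    for (i in seq_len(nrow(truth_de)))
      cond_mult[truth_de$subtype[i], truth_de$gene[i]] <-
        2^truth_de$log2fc[i]
  }

  # planted co-expression modules: member genes drawn disjointly
  truth_modules <- list()
  mods <- config$planted_modules
  if (length(mods)) {
    truth_modules <- with_seed(substream_seed(config$seed, 4L), {
      # members come from the better-expressed half of the panel: latent-factor
      # co-expression is only observable for genes with adequate counts
      avail <- setdiff(which(gene_base >= median(gene_base)),
                       match(unique(truth_de$gene %||% character()), genes))
      out <- list()
      for (i in seq_along(mods)) {
        m <- mods[[i]]
        if (length(avail) < m$size) stop("not enough genes free of DE truth for module", call. = FALSE)
        gidx <- sample(avail, m$size)
        avail <- setdiff(avail, gidx)
        # per-gene membership strength: hub genes load the latent factor
        # more strongly than peripheral ones, as in real co-expression
        # modules (continuous kME spectrum, scale-free-ish degrees)
        out[[paste0("module", i)]] <- list(
          genes = genes[gidx], loading = m$loading,
          gene_exponent = stats::runif(m$size, 0.6, 1.4),
          subtypes = m$subtypes, coupling = m$coupling %||% 0)
      }
      out
    })
  }

  shift <- setNames(rep(1, S), subtypes$level4)
  if (!is.null(config$composition_shifts))
    shift[config$composition_shifts$subtype] <- config$composition_shifts$ratio

  disp <- if (length(config$nb_dispersion) == 1L)
    rep(config$nb_dispersion, G) else config$nb_dispersion

  blocks <- vector("list", nrow(samples) * S)
  meta_blocks <- vector("list", nrow(samples) * S)
  bi <- 0L
  for (s in seq_len(nrow(samples))) {
    is_case <- samples$condition[s] == "case"
    for (t in seq_len(S)) {
      bi <- bi + 1L
      bseed <- substream_seed(config$seed, 10L, s, t)
      blk <- with_seed(bseed, {
        mu_t <- config$cells_per_subtype * if (is_case) shift[t] else 1
        n <- stats::rpois(1L, mu_t)
        if (n == 0L) return(NULL)
        rel <- gene_base * program[t, ]
        if (is_case) rel <- rel * cond_mult[t, ]
        relm <- matrix(rel, n, G, byrow = TRUE)
        for (m in truth_modules) {
          if (!is.null(m$subtypes) && !(subtypes$level4[t] %in% m$subtypes)) next
          f <- stats::rlnorm(n, meanlog = if (is_case) m$coupling else 0,
                             sdlog = m$loading)
          mi <- match(m$genes, genes)
          relm[, mi] <- relm[, mi] * exp(log(f) %o% m$gene_exponent)
        }
        lib <- stats::rlnorm(n, config$library_size$meanlog,
                             config$library_size$sdlog)
        mu <- relm / rowSums(relm) * lib
        lam <- mu * matrix(stats::rgamma(n * G, shape = rep(1 / disp, each = n),
                                         scale = rep(disp, each = n)), n, G)
        matrix(stats::rpois(n * G, lam), n, G)
      })
      if (is.null(blk)) next
      blocks[[bi]] <- blk
      meta_blocks[[bi]] <- data.frame(
        sample_id = samples$sample_id[s], condition = samples$condition[s],
        class = subtypes$class[t], level1 = subtypes$level1[t],
        level2 = subtypes$level2[t], level3 = subtypes$level3[t],
        level4 = subtypes$level4[t], stringsAsFactors = FALSE)[rep(1L, nrow(blk)), ]
    }
  }
  keep <- !vapply(blocks, is.null, logical(1))
  counts <- do.call(rbind, blocks[keep])
  meta <- do.call(rbind, meta_blocks[keep])
  meta$cell_id <- sprintf("cell%06d", seq_len(nrow(meta)))
  rownames(meta) <- meta$cell_id
  dimnames(counts) <- list(meta$cell_id, genes)

  truth <- list(
    genes = genes,
    de = truth_de,
    modules = truth_modules,
    composition = data.frame(subtype = subtypes$level4, ratio = unname(shift),
                             stringsAsFactors = FALSE),
    affected_ranking = if (is.null(aff) || !nrow(aff)) character(0) else
      aff$subtype[order(-(aff$n_de_genes * abs(aff$log2fc)), aff$subtype)],
    config = config
  )
  list(data = annotated_counts(Matrix::Matrix(counts, sparse = TRUE), meta),
       truth = truth)
}

#' Generate a gene-set collection with designated spiked terms
#'
#' Most terms are uniform random draws from the cohort's gene universe; a
#' designated subset over-samples the planted differentially expressed genes
#' at the given spike rate, providing fixtures with a known enrichment
#' signal. Also returns a curated-gene-list fixture (enriched for planted DE
#' genes) and a random autopsy-list fixture.
#'
#' @param truth truth record from [generate_cohort()].
#' @param n_terms number of terms (>= 1).
#' @param term_size_range integer range of term sizes.
#' @param enrichment_spike fraction of a spiked term's genes drawn from the
#'   planted DE genes.
#' @param n_spiked how many leading terms are spiked.
#' @param seed integer seed.
#' @return list with `gene_sets` (named list of character vectors), `spiked`
#'   (names of the spiked terms), `curated`, `autopsy`.
#' @export
generate_gene_sets <- function(truth, n_terms = 50L, term_size_range = c(10L, 40L),
                               enrichment_spike = 0.5, n_spiked = 3L, seed = 1L) {
  stopifnot(n_terms >= 1L)
  genes <- truth$genes
  if (max(term_size_range) > length(genes))
    stop("term size exceeds gene count", call. = FALSE)
  de_genes <- unique(truth$de$gene %||% character(0))
  n_spiked <- min(n_spiked, n_terms)
  if (!length(de_genes)) n_spiked <- 0L
  with_seed(substream_seed(seed, 21L), {
    size_pool <- seq(term_size_range[1], term_size_range[2])
    sizes <- if (length(size_pool) == 1L) rep(size_pool, n_terms) else
      sample(size_pool, n_terms, replace = TRUE)
    sets <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      if (i <= n_spiked && enrichment_spike > 0) {
        k <- min(round(enrichment_spike * sizes[i]), length(de_genes))
        spike <- sample(de_genes, k)
        rest <- sample(setdiff(genes, spike), sizes[i] - k)
        sets[[i]] <- sort(c(spike, rest))
      } else {
        sets[[i]] <- sort(sample(genes, sizes[i]))
      }
    }
    names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    curated <- unique(c(
      if (length(de_genes)) sample(de_genes, min(20L, length(de_genes))),
      sample(genes, 10L)))
    autopsy <- sample(genes, min(30L, length(genes)))
    list(gene_sets = sets,
         spiked = if (n_spiked) names(sets)[seq_len(n_spiked)] else character(0),
         curated = curated, autopsy = autopsy)
  })
}

#' Generate a synthetic smFISH per-cell intensity table
#'
#' Emulates integrated-density measurements of a target and a reference
#' channel in control and case cells across tissue sections, with
#' log-normal noise and multiplicative per-section intensity offsets (the
#' batch effect that reference-channel quantile normalization corrects).
#'
#' @param n_cells_per_group cells per group (scalar or length-2 vector,
#'   control then case).
#' @param group_means list with `target` (length-2: control, case means) and
#'   `reference` (scalar mean, condition-independent).
#' @param noise log-sd of the per-cell log-normal noise.
#' @param n_sections number of tissue sections per group.
#' @param section_sdlog log-sd of per-section intensity offsets.
#' @param seed integer seed.
#' @return data frame with cell_id, section_id, group,
#'   target_raw_intensity, reference_raw_intensity.
#' @export
generate_smfish_table <- function(n_cells_per_group = 50L,
                                  group_means = list(target = c(1000, 1000),
                                                     reference = 800),
                                  noise = 0.3, n_sections = 2L,
                                  section_sdlog = 0.2, seed = 1L) {
  if (any(unlist(group_means) <= 0))
    stop("group means must be positive", call. = FALSE)
  n <- rep(n_cells_per_group, length.out = 2L)
  with_seed(substream_seed(seed, 31L), {
    groups <- rep(c("control", "case"), n)
    sec_eff <- stats::rlnorm(2L * n_sections, 0, section_sdlog)
    section <- unlist(lapply(seq_len(2L), function(g)
      rep(seq_len(n_sections), length.out = n[g]) + (g - 1L) * n_sections))
    tgt_mean <- rep(group_means$target, n)
    target <- stats::rlnorm(sum(n), log(tgt_mean * sec_eff[section]), noise)
    reference <- stats::rlnorm(sum(n), log(group_means$reference *
                                             sec_eff[section]), noise)
    data.frame(
      cell_id = sprintf("fish%04d", seq_len(sum(n))),
      section_id = sprintf("sec%02d", section),
      group = groups,
      target_raw_intensity = target,
      reference_raw_intensity = reference,
      stringsAsFactors = FALSE)
  })
}
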