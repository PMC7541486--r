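#' Permutation test for cell-type composition change
#'
#' Computes each sample's within-sample subtype proportions and tests, per
#' subtype, the absolute difference in mean proportion between conditions
#' against a null built by permuting condition labels over samples (the
#' sample is the exchangeable unit). The p value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), so it is never 0; with
#' `exhaustive = TRUE` all distinct label assignments are enumerated
#' instead and p is the exact null fraction.
#'
#' @param data an [annotated_counts()].
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param level subtype annotation column.
#' @param exhaustive enumerate all condition-label assignments (feasible for
#'   small cohorts only).
#' @return A `composition_table`: list with `proportions` (sample x subtype),
#'   `p` (named per subtype), `statistic` (observed |difference in means|).
#' @export
composition_test <- function(data, n_perm = 1000L, seed = 1L,
                             level = "level4", exhaustive = FALSE) {
  stopifnot(inherits(data, "annotated_counts"))
  meta <- data$meta
  samples <- unique(meta$sample_id)
  cond <- meta$condition[match(samples, meta$sample_id)]
  if (sum(cond == "control") < 2L || sum(cond == "case") < 2L)
    stop("need >= 2 samples per condition", call. = FALSE)
  subtypes <- sort(unique(meta[[level]]))
  tab <- table(factor(meta$sample_id, samples), factor(meta[[level]], subtypes))
  prop <- tab / rowSums(tab)
  prop <- matrix(prop, nrow(tab), ncol(tab), dimnames = dimnames(tab))

  stat_for <- function(is_case)
    abs(colMeans(prop[is_case, , drop = FALSE]) -
        colMeans(prop[!is_case, , drop = FALSE]))
  obs <- stat_for(cond == "case")
  n_case <- sum(cond == "case")

  if (exhaustive) {
    combs <- utils::combn(length(samples), n_case)
    null <- apply(combs, 2L, function(ix) {
      z <- rep(FALSE, length(samples)); z[ix] <- TRUE; stat_for(z)
    })
    p <- rowMeans(null >= obs)  # includes the observed assignment
  } else {
    ge <- rep(0L, length(subtypes))
    with_seed(substream_seed(seed, 51L), {
      for (b in seq_len(n_perm)) {
        ix <- sample.int(length(samples), n_case)
        z <- rep(FALSE, length(samples)); z[ix] <- TRUE
        ge <- ge + (stat_for(z) >= obs)
      }
    })
    p <- (1 + ge) / (1 + n_perm)
  }
  structure(list(proportions = prop, p = setNames(as.numeric(p), subtypes),
                 statistic = setNames(as.numeric(obs), subtypes)),
            class = "composition_table")
}

#' Ordinal classification of composition p values
#'
#' The permutation p value is used as a continuous measure, not a binary
#' test: p < 0.2 marks a subtype "affected" (1), p < 0.05 "highly affected"
#' (2), and the smallest p per class is the single "top-1" (3); ties break
#' deterministically by subtype name.
#'
#' @param table a `composition_table` from [composition_test()].
#' @param class_partition named vector subtype -> class.
#' @return data frame: subtype, class, p, category.
#' @export
categorize_composition <- function(table, class_partition) {
  p <- table$p
  cls <- class_partition[names(p)]
  cat <- integer(length(p))
  cat[p < 0.2] <- 1L
  cat[p < 0.05] <- 2L
  cat <- assign_top1(cat, p, cls, lower_is_worse = TRUE)
  data.frame(subtype = names(p), class = unname(cls), p = unname(p),
             category = cat, stringsAsFactors = FALSE)
}
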