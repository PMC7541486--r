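#' Reference-channel intensity correction
#'
#' The correction factor of the normalized reference channel:
#' target_normalized = target * (reference_normalized / reference). Applied
#' on raw integrated densities, it is invariant to any multiplicative
#' rescaling applied jointly to reference and normalized reference.
#'
#' @param target,reference,reference_normalized numeric vectors.
#' @return corrected target intensities.
#' @export
apply_intensity_correction <- function(target, reference, reference_normalized) {
  stopifnot(all(reference > 0))
  target * (reference_normalized / reference)
}

# quantile normalization across unequal-size columns: each value is mapped
# through the mean of the per-section quantile functions at its own
# mid-rank probability (type-5 convention, so equal-size sections end up
# with identical sorted values)
quantile_normalize_groups <- function(x, group) {
  groups <- unique(group)
  out <- numeric(length(x))
  probs_of <- function(n) (seq_len(n) - 0.5) / n
  ref_fun <- function(p) {
    rowMeans(vapply(groups, function(g)
      stats::quantile(x[group == g], p, type = 5, names = FALSE),
      numeric(length(p))))
  }
  for (g in groups) {
    i <- which(group == g)
    r <- rank(x[i], ties.method = "average")
    out[i] <- ref_fun((r - 0.5) / length(i))
  }
  out
}

#' Normalize smFISH target intensity against a reference channel
#'
#' Raw integrated densities are log2-transformed; the reference channel
#' (condition-independent by design) is quantile-normalized across tissue
#' sections on the log2 scale to remove section-level intensity batch
#' effects; the correction factor reference_normalized / reference is then
#' applied to the raw-scale target. Cells with non-positive reference
#' signal are excluded (and recorded in the `excluded` attribute).
#'
#' @param tab data frame with columns section_id, group,
#'   target_raw_intensity, reference_raw_intensity.
#' @return `tab` with added columns reference_normalized,
#'   target_normalized, log2_target_normalized.
#' @export
normalize_target <- function(tab) {
  need <- c("section_id", "group", "target_raw_intensity",
            "reference_raw_intensity")
  stopifnot(all(need %in% names(tab)))
  if (length(unique(tab$group)) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  bad <- tab$reference_raw_intensity <= 0
  excluded <- tab[bad, , drop = FALSE]
  tab <- tab[!bad, , drop = FALSE]
  v_log <- log2(tab$reference_raw_intensity)
  v_norm_log <- quantile_normalize_groups(v_log, tab$section_id)
  tab$reference_normalized <- 2^v_norm_log
  tab$target_normalized <- apply_intensity_correction(
    tab$target_raw_intensity, tab$reference_raw_intensity,
    tab$reference_normalized)
  tab$log2_target_normalized <- log2(tab$target_normalized)
  attr(tab, "excluded") <- excluded
  tab
}

#' One-sided two-group comparison of intensity values
#'
#' Welch's t test (unequal variances, Satterthwaite degrees of freedom) or
#' the one-tailed Mann--Whitney test (exact when both groups have <= 20
#' values and no ties, otherwise normal approximation with tie correction).
#' `direction` states the alternative for case relative to control.
#'
#' @param values numeric vector.
#' @param group factor/character with levels control and case.
#' @param test `"welch"` or `"mann_whitney"`.
#' @param direction `"less"` (case < control) or `"greater"`.
#' @return list with `p`, `statistic`, `test`; constant pooled values give
#'   p = 1 with a flag.
#' @export
compare_groups <- function(values, group,
                           test = c("welch", "mann_whitney"),
                           direction = c("less", "greater")) {
  test <- match.arg(test)
  direction <- match.arg(direction)
  x <- values[group == "case"]
  y <- values[group == "control"]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(c(x, y)) == 0)
    return(list(p = 1, statistic = NA_real_, test = test,
                flag = "constant values"))
  if (test == "welch") {
    ht <- stats::t.test(x, y, alternative = direction, var.equal = FALSE)
  } else {
    exact <- max(length(x), length(y)) <= 20L && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = direction, exact = exact,
                         correct = !exact))
  }
  list(p = unname(ht$p.value), statistic = unname(ht$statistic), test = test)
}
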