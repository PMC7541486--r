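#' @importFrom stats median quantile sd cor var rnorm rpois rbinom runif
#' @importFrom stats p.adjust phyper pnorm pt setNames aggregate
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Mixes a global seed with integer stream indices so that independent
#' stages (or independent sample/subtype blocks within a stage) draw from
#' independent, individually reproducible streams. Changing the cells of
#' one block never perturbs another block's draws.
#'
#' @param seed integer global seed.
#' @param ... integer stream indices identifying the substream.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  x <- as.numeric(seed) %% 2147483647
  for (i in seq_along(idx)) {
    # 64-bit-safe multiplicative mixing in double precision (< 2^53)
    x <- (x * 48271 + as.numeric(idx[i]) * 16807 + i * 69621) %% 2147483647
  }
  as.integer(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' 40 percent trimmed mean with per-tail semantics
#'
#' Drops `floor(n * trim)` values from each tail before averaging, the
#' convention of [base::mean()]'s `trim` argument. With fewer than one
#' value remaining the median is returned.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed from each tail (default 0.4).
#' @return scalar mean of the retained values.
#' @export
trimmed_mean <- function(x, trim = 0.4) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- floor(n * trim)
  if (n - 2L * k < 1L) return(median(x))
  xs <- sort(x)
  mean(xs[(k + 1L):(n - k)])
}

#' Median absolute deviation
#'
#' MAD about the median, scaled by 1.4826 for consistency with the normal
#' standard deviation (the default of [stats::mad()]).
#'
#' @param x numeric vector.
#' @param constant scale constant (default 1.4826).
#' @return scalar MAD.
#' @export
mad_dev <- function(x, constant = 1.4826) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  constant * median(abs(x - median(x)))
}

# deterministic name-order tie-break: index of the extreme value, first by
# value then alphabetically by name
which_extreme <- function(x, names, max = TRUE) {
  stopifnot(length(x) == length(names))
  ord <- order(if (max) -x else x, names)
  ord[1L]
}
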