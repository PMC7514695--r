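#' Coarse-grain a signal by non-overlapping block means
#'
#' `y(t) = mean(x[((t-1)*eps + 1) : (t*eps)])` for `t = 1 ..
#' floor(N/eps)`. Scale factor 1 returns the input unchanged; trailing
#' samples that do not fill a block are dropped.
#'
#' @param x Numeric series.
#' @param eps Positive integer scale factor, at most `length(x)`.
#' @return Numeric series of length `floor(length(x)/eps)`.
#' @export
coarse_grain <- function(x, eps) {
  eps <- as.integer(eps)
  if (eps < 1L) stop("eps must be >= 1")
  n <- length(x)
  if (eps > n) stop("eps exceeds the series length")
  if (eps == 1L) return(as.numeric(x))
  nb <- n %/% eps
  colMeans(matrix(x[seq_len(nb * eps)], nrow = eps))
}

#' Sample entropy
#'
#' The negative log ratio of the (m+1)- to m-template match probabilities,
#' with templates compared in Chebyshev (maximum-coordinate) distance,
#' strict inequality `< r`, self-matches excluded. The tolerance `r` is
#' absolute here; [multiscale_entropy()] handles the conventional
#' fraction-of-SD scaling.
#'
#' @param y Numeric series.
#' @param m Template length (default 2).
#' @param r Absolute tolerance (> 0).
#' @return Sample entropy, or `NA` when either template count is zero
#'   (entropy undefined).
#' @export
sample_entropy <- function(y, m = 2L, r) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("series contains non-finite values")
  .sampen_core(y, as.integer(m), r)
}

#' Multiscale-entropy parameters
#'
#' @param m Template length.
#' @param r Tolerance as a fraction of the SD of the original (scale-1)
#'   signal; the absolute tolerance `r * sd(x)` is held fixed across scales.
#' @param scales Integer scale factors.
#' @return A list of class `mse_params`.
#' @export
mse_params <- function(m = 2L, r = 0.15, scales = 1:80) {
  if (m < 1L) stop("m must be >= 1")
  if (r <= 0) stop("r must be positive")
  scales <- as.integer(scales)
  if (any(scales < 1L)) stop("scales must be positive integers")
  structure(list(m = as.integer(m), r = r, scales = scales),
            class = "mse_params")
}

#' Multiscale entropy of one signal
#'
#' Sample entropy of every coarse-grained version of `x`, using a single
#' absolute tolerance `params$r * sd(x)` fixed from the raw signal, so that
#' MSE at scale 1 equals the plain sample entropy of `x` and the measure is
#' invariant to affine rescaling of the signal.
#'
#' @param x Numeric series at 1 kHz (one sample per ms).
#' @param params An [mse_params()].
#' @return Named numeric vector of sample entropies, one per scale (names
#'   `"1"`, `"2"`, ...); entries are `NA` where undefined.
#' @export
multiscale_entropy <- function(x, params = mse_params()) {
  stopifnot(inherits(params, "mse_params"))
  x <- as.numeric(x)
  if (length(x) < max(params$scales) * (params$m + 2L))
    stop("series too short for the largest scale factor")
  s <- stats::sd(x)
  if (s == 0) {
    out <- rep(0, length(params$scales))
    names(out) <- params$scales
    return(out)
  }
  r_abs <- params$r * s
  out <- vapply(params$scales, function(eps)
    .sampen_core(coarse_grain(x, eps), params$m, r_abs), numeric(1))
  names(out) <- params$scales
  out
}

#' Summed-complexity index
#'
#' Sum of sample entropy over the configured scale factors; the per-group
#' scalar used to rank groups by complexity of activity.
#'
#' @param mse_row Numeric vector from [multiscale_entropy()].
#' @return The sum, or `NA` (with a warning) if any entry is undefined.
#' @export
complexity_index <- function(mse_row) {
  if (anyNA(mse_row)) {
    warning("undefined sample entropy at some scale; complexity index is NA")
    return(NA_real_)
  }
  sum(mse_row)
}

#' Multiscale entropy of every row of a signal matrix
#'
#' @param signals Matrix with one signal per row (e.g. a LAP matrix).
#' @param params An [mse_params()].
#' @return Matrix, rows = signals, columns = scales.
#' @export
mse_matrix <- function(signals, params = mse_params()) {
  t(apply(signals, 1L, multiscale_entropy, params = params))
}
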