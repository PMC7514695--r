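#' Local averaged potential from a membrane-history matrix
#'
#' The LAP of a group is the mean membrane potential of its excitatory
#' neurons, with spike samples capped at +30 mV. [run_simulation()] records
#' it on the fly; this function computes the same quantity from an explicit
#' neurons x time membrane matrix, for analysis-only workflows and tests.
#'
#' @param v_hist Numeric matrix, one row per neuron, one column per ms.
#' @param group Integer group id per neuron (row).
#' @param is_exc Logical, `TRUE` for excitatory neurons.
#' @return Groups x ms LAP matrix (mV).
#' @export
compute_lap <- function(v_hist, group, is_exc) {
  stopifnot(is.matrix(v_hist), nrow(v_hist) == length(group),
            length(group) == length(is_exc))
  v_hist <- pmin(v_hist, 30)
  gs <- sort(unique(group))
  out <- matrix(NA_real_, length(gs), ncol(v_hist))
  for (i in seq_along(gs)) {
    rows <- which(group == gs[i] & is_exc)
    if (length(rows) == 0L)
      stop("group ", gs[i], " has no excitatory neurons")
    out[i, ] <- colMeans(v_hist[rows, , drop = FALSE])
  }
  rownames(out) <- gs
  out
}

#' Per-group firing rates
#'
#' Mean rate in Hz over a time window, separately for excitatory and
#' inhibitory neurons: spike count / (number of neurons of that type x
#' window length in seconds).
#'
#' @param raster Data frame `(time_ms, neuron)`.
#' @param window `c(start, end)` ms, end exclusive.
#' @param neurons Neuron table with `id`, `group`, `type`.
#' @return Data frame per group: `group`, `rate_exc`, `rate_inh` (Hz).
#' @export
firing_rates <- function(raster, window, neurons) {
  dur_s <- (window[2] - window[1]) / 1000
  if (dur_s <= 0) stop("window must have positive length")
  gs <- sort(unique(neurons$group))
  sel <- raster$time_ms >= window[1] & raster$time_ms < window[2]
  sp <- raster$neuron[sel]
  sp_group <- neurons$group[sp]
  sp_exc <- neurons$type[sp] == "exc"
  n_exc <- tapply(neurons$type == "exc", neurons$group, sum)
  n_inh <- tapply(neurons$type == "inh", neurons$group, sum)
  cnt <- function(mask) {
    tab <- table(factor(sp_group[mask], levels = gs))
    as.numeric(tab)
  }
  data.frame(
    group = gs,
    rate_exc = cnt(sp_exc) / (as.numeric(n_exc[as.character(gs)]) * dur_s),
    rate_inh = cnt(!sp_exc) / (as.numeric(n_inh[as.character(gs)]) * dur_s)
  )
}

#' Amplitude spectrum of a 1 kHz signal
#'
#' Mean-removed single-sided amplitude spectrum up to the Nyquist frequency
#' (500 Hz), normalised so a pure sinusoid of amplitude A shows a peak of
#' approximately A at its frequency.
#'
#' @param x Numeric series sampled at 1000 Hz.
#' @param fs Sampling rate in Hz.
#' @return Data frame `(frequency, amplitude)`; frequency 0 is excluded.
#' @export
amplitude_spectrum <- function(x, fs = 1000) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("signal too short")
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  xf <- stats::fft(x - mean(x))
  half <- seq_len(n %/% 2L)
  data.frame(
    frequency = (half) * fs / n,
    amplitude = 2 * Mod(xf[half + 1L]) / n
  )
}

#' Band peaks of an amplitude spectrum
#'
#' Within each half-open frequency band `[lo, hi)`, the frequency and
#' amplitude of the largest spectral bin; ties break to the lower frequency.
#'
#' @param spectrum Data frame from [amplitude_spectrum()].
#' @param bands Numeric matrix or data frame with columns `lo`, `hi`
#'   (Hz). Default: the 0-20, 20-40, 40-60 Hz bands.
#' @return Data frame per band: `lo`, `hi`, `peak_frequency`,
#'   `peak_amplitude`.
#' @export
band_peaks <- function(spectrum,
                       bands = data.frame(lo = c(0, 20, 40),
                                          hi = c(20, 40, 60))) {
  bands <- as.data.frame(bands)
  out <- bands
  out$peak_frequency <- NA_real_
  out$peak_amplitude <- NA_real_
  for (i in seq_len(nrow(bands))) {
    sel <- spectrum$frequency >= bands$lo[i] & spectrum$frequency < bands$hi[i]
    if (!any(sel)) stop("band [", bands$lo[i], ", ", bands$hi[i],
                        ") contains no spectral bins")
    f <- spectrum$frequency[sel]
    a <- spectrum$amplitude[sel]
    k <- which.max(a) # which.max returns the first (lowest-frequency) tie
    out$peak_frequency[i] <- f[k]
    out$peak_amplitude[i] <- a[k]
  }
  out
}

#' Peak envelope of a spectrum
#'
#' Piecewise-linear interpolation through the local maxima of the amplitude
#' spectrum (endpoints included as anchors), the curve used to draw smooth
#' spectral outlines.
#'
#' @param spectrum Data frame from [amplitude_spectrum()].
#' @return Data frame `(frequency, envelope)` on the same frequency grid.
#' @export
peak_envelope <- function(spectrum) {
  a <- spectrum$amplitude
  f <- spectrum$frequency
  n <- length(a)
  if (n < 3L) return(data.frame(frequency = f, envelope = a))
  is_max <- c(FALSE, a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n],
              FALSE)
  anchors <- unique(c(1L, which(is_max), n))
  env <- stats::approx(f[anchors], a[anchors], xout = f)$y
  data.frame(frequency = f, envelope = env)
}

#' Read a 1-D signal from a plain-text file
#'
#' One sample per line (or a single-column CSV), for the analysis-only
#' path: externally supplied LAP-like signals can be fed straight into
#' [multiscale_entropy()] and [amplitude_spectrum()].
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_signal <- function(path) {
  x <- utils::read.table(path, header = FALSE)[[1]]
  as.numeric(x)
}
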