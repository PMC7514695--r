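#' Surrogate 1-D signals with known complexity structure
#'
#' Seed-deterministic generators for signals that stand in for local
#' averaged potentials when exercising the analysis chain: a constant, white
#' Gaussian noise, 1/f (pink) noise via spectral shaping, and sinusoid
#' mixtures with optional additive noise. All are nominally sampled at
#' 1 kHz (one sample per ms).
#'
#' @param kind One of `"constant"`, `"white_gaussian"`, `"one_over_f"`,
#'   `"sine_mix"`.
#' @param length_ms Signal length in samples (>= 100).
#' @param seed Integer seed.
#' @param sd Standard deviation of the noise component.
#' @param mean Signal mean (baseline).
#' @param freqs,amps Sinusoid frequencies (Hz, below the 500 Hz Nyquist)
#'   and amplitudes, for `"sine_mix"`.
#' @param noise_sd Additive white-noise SD for `"sine_mix"`.
#' @param exponent Power-spectral exponent for `"one_over_f"`: power scales
#'   as `f^(-exponent)` (amplitude as `f^(-exponent/2)`).
#' @return Numeric vector of length `length_ms`.
#' @export
surrogate_signal <- function(kind = c("constant", "white_gaussian",
                                      "one_over_f", "sine_mix"),
                             length_ms = 10000L, seed = 1L,
                             sd = 1, mean = 0,
                             freqs = 30, amps = 1, noise_sd = 0,
                             exponent = 1) {
  kind <- match.arg(kind)
  n <- as.integer(length_ms)
  if (n < 100L) stop("length_ms must be at least 100")
  if (any(freqs >= 500)) stop("frequencies must be below the 500 Hz Nyquist")
  withr_seed(seed, switch(
    kind,
    constant = rep(mean, n),
    white_gaussian = mean + stats::rnorm(n, sd = sd),
    one_over_f = {
      white <- stats::rnorm(n)
      xf <- stats::fft(white)
      k <- 0:(n - 1)
      m <- pmin(k, n - k) # folded frequency index, symmetric about Nyquist
      m[1] <- 1 # DC bin: any finite value, removed by standardization
      shaped <- Re(stats::fft(xf * m^(-exponent / 2), inverse = TRUE)) / n
      shaped <- shaped - base::mean(shaped)
      mean + sd * shaped / stats::sd(shaped)
    },
    sine_mix = {
      t_s <- (seq_len(n) - 1) / 1000
      s <- rowSums(vapply(seq_along(freqs), function(i)
        amps[i] * sin(2 * pi * freqs[i] * t_s), numeric(n)))
      if (noise_sd > 0) s <- s + stats::rnorm(n, sd = noise_sd)
      mean + s
    }
  ))
}

#' Catalogue of toy directed weighted connectivities
#'
#' Small graphs with analytically known clustering, path and degree values,
#' used as fixtures for the graph-metric oracles:
#' \describe{
#'   \item{reciprocal_triangle}{3 nodes, every ordered pair linked, unit
#'     weights; clustering 1 everywhere.}
#'   \item{directed_cycle_3}{pure cycle A-B-C-A, unit weights; clustering
#'     0.5 everywhere.}
#'   \item{directed_cycle_10}{10-node directed ring; per-node mean path
#'     `mean(1:9) = 5`.}
#'   \item{star_8}{node 1 reciprocally linked to nodes 2..8; hub degree 7.}
#'   \item{complete_5}{complete reciprocal 5-node graph, unit weights.}
#'   \item{random_8}{fixed-seed random weighted digraph on 8 nodes
#'     (edge probability 0.4, uniform weights).}
#' }
#'
#' @param name Catalogue entry name.
#' @return Directed weighted adjacency matrix.
#' @export
toy_connectivity <- function(name = c("reciprocal_triangle",
                                      "directed_cycle_3",
                                      "directed_cycle_10", "star_8",
                                      "complete_5", "random_8")) {
  name <- match.arg(name)
  cyc <- function(n) {
    W <- matrix(0, n, n)
    W[cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))] <- 1
    W
  }
  switch(name,
    reciprocal_triangle = matrix(1, 3, 3) - diag(3),
    directed_cycle_3 = cyc(3),
    directed_cycle_10 = cyc(10),
    star_8 = {
      W <- matrix(0, 8, 8)
      W[1, 2:8] <- 1
      W[2:8, 1] <- 1
      W
    },
    complete_5 = matrix(1, 5, 5) - diag(5),
    random_8 = withr_seed(42L, {
      W <- matrix(stats::runif(64), 8, 8) * (matrix(stats::runif(64), 8, 8) < 0.4)
      diag(W) <- 0
      W
    })
  )
}

#' Fluctuation-preserving weight scale for reduced presets
#'
#' Downscaling the neuron groups cuts every neuron's synaptic fan-in, which
#' would quench both the mean and the variance of its recurrent input if
#' the full-scale weights were kept. Reduced presets therefore multiply the
#' weights of each afferent class by the square root of its fan-in
#' reduction (the balanced-network `1/sqrt(K)` convention), which preserves
#' the size of input fluctuations -- the quantity that governs whether
#' recurrent activity can ignite and sustain itself. STDP amplitudes and
#' the flush bias live on the weight scale and are multiplied by the same
#' excitatory factor.
#'
#' @param n_exc,n_inh,c_intra,c_inter,k Reduced-model structure.
#' @return List with `s_exc` and `s_inh`, the excitatory and inhibitory
#'   weight multipliers relative to the full-scale model.
#' @export
fanin_weight_scale <- function(n_exc, n_inh, c_intra, c_inter, k) {
  kfull <- fanin_means(800, 200, 100, 3, 6)
  kred <- fanin_means(n_exc, n_inh, c_intra, c_inter, k)
  list(s_exc = sqrt(kfull$exc / kred$exc),
       s_inh = sqrt(kfull$inh / kred$inh))
}

# expected afferent counts at an excitatory neuron: excitatory afferents
# (intra + lattice inter) and inhibitory afferents (intra only)
fanin_means <- function(n_exc, n_inh, c_intra, c_inter, k) {
  n <- n_exc + n_inh
  list(
    exc = n_exc * c_intra / (n - 1) + k * n_exc * c_inter / n,
    inh = n_inh * c_intra / n_exc
  )
}

#' Reduced-scale model and study presets
#'
#' Scaled-down configurations that preserve the structural ratios of the
#' full model (4:1 excitatory:inhibitory, intra fan-out well below the
#' group size, lattice degree `k = 6`, nested schedule
#' `t_stdp < t_tonic < t_total`) while remaining runnable on one CPU:
#' \describe{
#'   \item{full}{the full-scale setting: 100 groups x (800 + 200)
#'     neurons, fan-outs 100/3, 1200 s with plasticity for 1000 s and
#'     input for 1100 s, entropy scales 1-80.}
#'   \item{desk}{30 groups x (80 + 20) neurons, intra fan-out 20, 300 s
#'     total / 250 s plasticity / 280 s input, scales 1-40.}
#'   \item{smoke}{10 groups x (40 + 10) neurons, intra fan-out 10, 60 s
#'     total / 40 s plasticity / 50 s input, scales 1-10.}
#' }
#'
#' @param preset `"full"`, `"desk"` or `"smoke"`.
#' @param seed Base seed stored in the configuration.
#' @return List with `model` (a [model_config()]) and `mse`
#'   (an [mse_params()]).
#' @export
desk_config <- function(preset = c("desk", "smoke", "full"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    full = list(
      model = model_config(seed = seed),
      mse = mse_params(scales = 1:80)
    ),
    desk = list(
      model = scaled_model(
        n_groups = 30L, n_exc = 80L, n_inh = 20L, c_intra = 20L,
        t_total = 300, t_tonic = 280, t_stdp = 250, seed = seed
      ),
      mse = mse_params(scales = 1:40)
    ),
    smoke = list(
      model = scaled_model(
        n_groups = 10L, n_exc = 40L, n_inh = 10L, c_intra = 10L,
        t_total = 60, t_tonic = 50, t_stdp = 40, seed = seed
      ),
      mse = mse_params(scales = 1:10)
    )
  )
}

# reduced model with fluctuation-preserving weights (see
# fanin_weight_scale); c_inter and k keep their full-scale values
scaled_model <- function(n_groups, n_exc, n_inh, c_intra,
                         t_total, t_tonic, t_stdp, seed,
                         c_inter = 3L, k = 6L) {
  s <- fanin_weight_scale(n_exc, n_inh, c_intra, c_inter, k)
  model_config(
    n_groups = n_groups, n_exc = n_exc, n_inh = n_inh,
    c_intra = c_intra, c_inter = c_inter, k = k,
    w_init_exc = 6 * s$s_exc, w_init_inh = -5 * s$s_inh,
    w_upper = 10 * s$s_exc,
    stdp = stdp_params(a_plus = 0.1 * s$s_exc, a_minus = 0.12 * s$s_exc,
                       flush_bias = 0.01 * s$s_exc),
    t_total = t_total, t_tonic = t_tonic, t_stdp = t_stdp, seed = seed
  )
}

#' Study configuration for a named preset
#'
#' @param preset Scale preset name, see [desk_config()].
#' @param p_ws Probabilities to sweep.
#' @param n_sims Replicates per probability.
#' @param seed Base seed.
#' @return A [study_config()].
#' @export
preset_study <- function(preset = "desk", p_ws = c(0, 1), n_sims = 1L,
                         seed = 1L) {
  pc <- desk_config(preset, seed = seed)
  study_config(p_ws = p_ws, n_sims = n_sims, base = pc$model,
               mse = pc$mse, seed = seed)
}

#' Write a surrogate signal to a plain-text file
#'
#' One sample per line, readable back with [read_signal()].
#'
#' @param x Numeric signal.
#' @param path Output file path.
#' @export
write_signal <- function(x, path) {
  utils::write.table(data.frame(x), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
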