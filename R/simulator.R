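#' Simulation schedule
#'
#' Nested windows of the run, in milliseconds: plasticity active on
#' `[0, t_stdp)`, tonic input on `[0, t_tonic)`, the remainder
#' `[t_tonic, t_total)` is the input-free (resting-state-like) analysis
#' window.
#'
#' @param cfg A [model_config()] (times are taken from it, in seconds).
#' @return A list of class `sim_schedule` with `t_total_ms`, `t_tonic_ms`,
#'   `t_stdp_ms`, `analysis_window` (c(start, end), ms).
#' @export
sim_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  tt <- as.integer(round(cfg$t_total * 1000))
  tn <- as.integer(round(cfg$t_tonic * 1000))
  ts <- as.integer(round(cfg$t_stdp * 1000))
  structure(list(t_total_ms = tt, t_tonic_ms = tn, t_stdp_ms = ts,
                 analysis_window = c(tn, tt)),
            class = "sim_schedule")
}

#' Run the grouped-network simulation
#'
#' Executes the full schedule on a built network: 1 ms time steps,
#' current-based delayed deliveries, tonic input until `t_tonic`, STDP
#' weight updates (per-second flushes) until `t_stdp`, and nothing but
#' recurrent dynamics afterwards. Deterministic given `seed`.
#'
#' @param network A `grouped_network` from [build_network()].
#' @param seed Integer seed for the input stream (defaults to the config
#'   seed).
#' @param stdp Logical; disable to run the no-plasticity control.
#' @param lap_from_ms Record the local averaged potential from this
#'   millisecond on (default 0 = full run; use the analysis-window start to
#'   save memory on long runs).
#' @param spikes_from_ms Record raster spikes from this millisecond on.
#' @return An object of class `sim_result`: list with
#'   \describe{
#'     \item{raster}{data frame `(time_ms, neuron)` of spikes;}
#'     \item{lap}{`lap_matrix`: groups x ms matrix of mean excitatory
#'       membrane potential (mV, spike samples capped at +30);}
#'     \item{weights}{list of synapse-weight vectors `initial`,
#'       `post_stdp` (at the end of the plasticity window) and `final`,
#'       aligned with `network$synapses`;}
#'     \item{schedule, network, seed}{run provenance.}
#'   }
#' @export
run_simulation <- function(network, seed = NULL, stdp = TRUE,
                           lap_from_ms = 0L, spikes_from_ms = 0L) {
  stopifnot(inherits(network, "grouped_network"))
  cfg <- network$config
  if (is.null(seed)) seed <- cfg$seed
  sched <- sim_schedule(cfg)
  nr <- network$neurons
  sy <- network$synapses
  res <- withr_seed(seed * 7L + 5L, .sim_core(
    nr$a, nr$b, nr$c, nr$d, nr$v0, nr$u0,
    nr$group, nr$type == "exc",
    sy$pre, sy$post, sy$weight, sy$delay, sy$plastic,
    cfg$n_groups, sched$t_total_ms, sched$t_tonic_ms, sched$t_stdp_ms,
    cfg$tonic_current, cfg$tonic_per_group,
    isTRUE(stdp),
    cfg$stdp$a_plus, cfg$stdp$a_minus, cfg$stdp$tau,
    cfg$stdp$flush_bias, cfg$stdp$flush_decay, cfg$w_upper,
    as.integer(lap_from_ms), as.integer(spikes_from_ms)
  ))
  lap <- res$lap
  attr(lap, "from_ms") <- res$lap_from_ms
  class(lap) <- c("lap_matrix", class(lap))
  structure(
    list(
      raster = data.frame(time_ms = res$spike_t, neuron = res$spike_id),
      lap = lap,
      weights = list(initial = sy$weight,
                     post_stdp = res$weights_post_stdp,
                     final = res$weights_final,
                     flush_range = res$flush_weight_range,
                     n_flushes = res$n_flushes),
      schedule = sched,
      network = network,
      seed = seed
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Simulation: %d ms, %d spikes recorded, LAP %d groups x %d ms\n",
    x$schedule$t_total_ms, nrow(x$raster), nrow(x$lap), ncol(x$lap)
  ))
  invisible(x)
}

#' Slice a LAP matrix to a time window
#'
#' @param lap A `lap_matrix` (groups x ms, with a `from_ms` attribute).
#' @param window `c(start, end)` in ms, end exclusive, absolute run time.
#' @return A plain matrix, groups x window length.
#' @export
lap_window <- function(lap, window) {
  from <- attr(lap, "from_ms")
  if (is.null(from)) from <- 0L
  lo <- window[1] - from
  hi <- window[2] - from
  if (lo < 0L || hi > ncol(lap)) stop("window outside the recorded LAP range")
  unclass(lap)[, (lo + 1L):hi, drop = FALSE]
}
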