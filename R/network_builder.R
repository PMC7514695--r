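#' Microscopic model configuration
#'
#' Holds every parameter needed to instantiate and simulate the grouped
#' spiking network: population sizes, fan-outs, initial weights, conduction
#' delays and the simulation schedule. Defaults are the full-scale study
#' settings (100 groups of 800 excitatory + 200 inhibitory neurons, 1200 s);
#' use [desk_config()] for reduced presets that run on a workstation.
#'
#' @param n_groups Number of neuron groups.
#' @param n_exc,n_inh Excitatory / inhibitory neurons per group.
#' @param c_intra Intraconnection fan-out of every neuron (within its group).
#' @param c_inter Interconnection fan-out of an excitatory neuron per
#'   adjacent group in the fundamental network (`inter_per_neighbor = TRUE`),
#'   or in total split across neighbours when `FALSE`.
#' @param k Lattice degree of the fundamental network.
#' @param w_init_exc,w_init_inh Initial excitatory (positive) and inhibitory
#'   (negative) synaptic weights.
#' @param w_upper Upper bound for plastic (excitatory) weights.
#' @param delay_intra_exc Integer delay range (ms) for excitatory
#'   intraconnections; sampled uniformly on `delay_intra_exc[1]:delay_intra_exc[2]`.
#' @param delay_intra_inh Fixed delay (ms) of inhibitory intraconnections.
#' @param delay_inter_exc Integer delay range (ms) for interconnections.
#' @param t_total,t_tonic,t_stdp Total simulation time, tonic-input duration
#'   and plasticity duration, all in seconds, with
#'   `t_stdp <= t_tonic <= t_total`. The analysis window is
#'   `[t_tonic, t_total)`.
#' @param tonic_current Amplitude of the tonic current pulse (model units).
#' @param tonic_per_group Neurons per group receiving the pulse each
#'   millisecond.
#' @param stdp STDP constants, see [stdp_params()].
#' @param inter_per_neighbor Interpretation of `c_inter` (see above).
#' @param seed Base integer seed; wiring, heterogeneity and input use
#'   distinct streams derived from it.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_groups = 100L, n_exc = 800L, n_inh = 200L,
                         c_intra = 100L, c_inter = 3L, k = 6L,
                         w_init_exc = 6, w_init_inh = -5, w_upper = 10,
                         delay_intra_exc = c(1L, 20L), delay_intra_inh = 1L,
                         delay_inter_exc = c(10L, 30L),
                         t_total = 1200, t_tonic = 1100, t_stdp = 1000,
                         tonic_current = 20, tonic_per_group = 1L,
                         stdp = stdp_params(),
                         inter_per_neighbor = TRUE, seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups), n_exc = as.integer(n_exc),
    n_inh = as.integer(n_inh), c_intra = as.integer(c_intra),
    c_inter = as.integer(c_inter), k = as.integer(k),
    w_init_exc = w_init_exc, w_init_inh = w_init_inh, w_upper = w_upper,
    delay_intra_exc = as.integer(delay_intra_exc),
    delay_intra_inh = as.integer(delay_intra_inh),
    delay_inter_exc = as.integer(delay_inter_exc),
    t_total = t_total, t_tonic = t_tonic, t_stdp = t_stdp,
    tonic_current = tonic_current,
    tonic_per_group = as.integer(tonic_per_group),
    stdp = stdp, inter_per_neighbor = isTRUE(inter_per_neighbor),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_groups < 1L || n_exc < 1L || n_inh < 1L) stop("counts must be positive")
    if (w_init_exc <= 0) stop("w_init_exc must be positive")
    if (w_init_inh >= 0) stop("w_init_inh must be negative")
    if (w_init_exc > w_upper) stop("w_init_exc must not exceed w_upper")
    if (!(t_stdp <= t_tonic && t_tonic <= t_total))
      stop("schedule must satisfy t_stdp <= t_tonic <= t_total")
    if (c_intra >= n_exc + n_inh)
      stop("c_intra must be below the group size (no self-connections)")
    if (c_intra > n_exc)
      stop("c_intra must not exceed n_exc (inhibitory neurons target excitatory only)")
  })
  structure(cfg, class = "model_config")
}

#' STDP parameters
#'
#' Additive pair-based STDP with exponential windows, accumulated into a
#' per-synapse derivative that is flushed into the weights once per simulated
#' second: `w <- clip(w + bias + sd, 0, w_upper)`, `sd <- decay * sd`.
#'
#' @param a_plus Potentiation amplitude per pre-before-post pairing.
#' @param a_minus Depression amplitude per post-before-pre pairing.
#' @param tau Time constant (ms) of both exponential windows.
#' @param flush_bias Constant drift added at each per-second flush.
#' @param flush_decay Multiplicative decay of the derivative at each flush.
#' @return A list of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.1, a_minus = 0.12, tau = 20,
                        flush_bias = 0.01, flush_decay = 0.9) {
  structure(list(a_plus = a_plus, a_minus = a_minus, tau = tau,
                 flush_bias = flush_bias, flush_decay = flush_decay),
            class = "stdp_params")
}

#' Build the neuron populations of every group
#'
#' Per group, `n_exc` regular-spiking excitatory neurons and `n_inh`
#' fast-spiking inhibitory neurons with the standard heterogeneous
#' parameterization: excitatory `(a,b) = (0.02, 0.2)`,
#' `(c,d) = (-65 + 15 r^2, 8 - 6 r^2)`; inhibitory
#' `(a,b) = (0.02 + 0.08 r, 0.25 - 0.05 r)`, `(c,d) = (-65, 2)`, with `r`
#' uniform on `(0,1)` per neuron. All neurons start at `v = -65` mV,
#' `u = b * v`.
#'
#' @param cfg A [model_config()]. Uses the current RNG stream.
#' @return A data frame with one row per neuron: `id`, `group`, `type`
#'   (`"exc"`/`"inh"`), `a`, `b`, `c`, `d`, `v0`, `u0`.
#' @export
build_groups <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  n_per <- cfg$n_exc + cfg$n_inh
  n <- cfg$n_groups * n_per
  group <- rep(seq_len(cfg$n_groups), each = n_per)
  type <- rep(rep(c("exc", "inh"), c(cfg$n_exc, cfg$n_inh)), cfg$n_groups)
  r <- stats::runif(n)
  exc <- type == "exc"
  a <- ifelse(exc, 0.02, 0.02 + 0.08 * r)
  b <- ifelse(exc, 0.2, 0.25 - 0.05 * r)
  cc <- ifelse(exc, -65 + 15 * r^2, -65)
  d <- ifelse(exc, 8 - 6 * r^2, 2)
  data.frame(
    id = seq_len(n), group = group, type = type,
    a = a, b = b, c = cc, d = d,
    v0 = -65, u0 = b * -65
  )
}

# sample `size` distinct values from `pool` (no replacement)
sample_targets <- function(pool, size) pool[sample.int(length(pool), size)]

#' Wire intraconnections
#'
#' Every excitatory neuron connects to `c_intra` distinct neurons of its own
#' group (never itself); every inhibitory neuron connects to `c_intra`
#' distinct excitatory neurons of its group. Excitatory intra synapses get
#' weight `w_init_exc`, an integer delay uniform on the configured range and
#' the plastic flag; inhibitory synapses get `w_init_inh`, the fixed
#' inhibitory delay and are non-plastic.
#'
#' @param neurons Output of [build_groups()].
#' @param cfg A [model_config()]. Uses the current RNG stream.
#' @return Synapse data frame: `pre`, `post`, `weight`, `delay`, `kind`
#'   (`"intra"`), `plastic`.
#' @export
wire_intra <- function(neurons, cfg) {
  n_per <- cfg$n_exc + cfg$n_inh
  pre_list <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    ids <- neurons$id[neurons$group == g]
    exc_ids <- ids[neurons$type[ids] == "exc"]
    posts <- matrix(0L, n_per, cfg$c_intra)
    for (i in seq_along(ids)) {
      src <- ids[i]
      pool <- if (neurons$type[src] == "exc") setdiff(ids, src) else exc_ids
      posts[i, ] <- sample_targets(pool, cfg$c_intra)
    }
    pre_list[[g]] <- data.frame(
      pre = rep(ids, each = cfg$c_intra),
      post = as.integer(t(posts))
    )
  }
  syn <- do.call(rbind, pre_list)
  pre_exc <- neurons$type[syn$pre] == "exc"
  syn$weight <- ifelse(pre_exc, cfg$w_init_exc, cfg$w_init_inh)
  dr <- cfg$delay_intra_exc
  syn$delay <- ifelse(
    pre_exc,
    sample.int(dr[2] - dr[1] + 1L, nrow(syn), replace = TRUE) + dr[1] - 1L,
    cfg$delay_intra_inh
  )
  syn$kind <- "intra"
  syn$plastic <- pre_exc
  syn
}

#' Wire interconnections along the fundamental network
#'
#' For each fundamental edge and each direction, every excitatory neuron of
#' the source group connects to `c_inter` distinct neurons (of either type)
#' of the destination group, with weight `w_init_exc`, an integer delay
#' uniform on the inter range, and the plastic flag. Inhibitory neurons have
#' no interconnections; group pairs without a fundamental edge get none.
#'
#' @param neurons Output of [build_groups()].
#' @param fundamental A `fundamental_network` on `cfg$n_groups` nodes.
#' @param cfg A [model_config()]. Uses the current RNG stream.
#' @return Synapse data frame as in [wire_intra()], with `kind = "inter"`.
#' @export
wire_inter <- function(neurons, fundamental, cfg) {
  stopifnot(inherits(fundamental, "fundamental_network"))
  if (fundamental$n_groups != cfg$n_groups)
    stop("fundamental network and model_config disagree on n_groups")
  edges <- fundamental$edges
  # directed pairs: both orientations of every undirected edge
  pairs <- rbind(edges, edges[, c(2L, 1L), drop = FALSE])
  if (nrow(pairs) == 0L) {
    return(data.frame(pre = integer(), post = integer(), weight = numeric(),
                      delay = integer(), kind = character(),
                      plastic = logical()))
  }
  group_ids <- split(neurons$id, neurons$group)
  exc_by_group <- lapply(group_ids, function(ids)
    ids[neurons$type[ids] == "exc"])
  fanout <- cfg$c_inter
  # under the split reading, c_inter is a total budget divided across neighbours
  deg <- tabulate(c(edges), nbins = cfg$n_groups)
  out <- vector("list", nrow(pairs))
  for (pth in seq_len(nrow(pairs))) {
    src_g <- pairs[pth, 1L]
    dst_g <- pairs[pth, 2L]
    pres <- exc_by_group[[src_g]]
    pool <- group_ids[[dst_g]]
    n_t <- if (cfg$inter_per_neighbor) fanout else
      max(1L, fanout %/% max(1L, deg[src_g]))
    posts <- vapply(pres, function(p) sample_targets(pool, n_t),
                    integer(n_t))
    out[[pth]] <- data.frame(
      pre = rep(pres, each = n_t),
      post = as.integer(posts)
    )
  }
  syn <- do.call(rbind, out)
  dr <- cfg$delay_inter_exc
  syn$weight <- cfg$w_init_exc
  syn$delay <- sample.int(dr[2] - dr[1] + 1L, nrow(syn), replace = TRUE) +
    dr[1] - 1L
  syn$kind <- "inter"
  syn$plastic <- TRUE
  syn
}

#' Build the full grouped network
#'
#' Composes [build_groups()], [wire_intra()] and [wire_inter()] under seeds
#' derived from `cfg$seed` (separate streams for heterogeneity, intra wiring
#' and inter wiring, so changing one leaves the others untouched).
#'
#' @param cfg A [model_config()].
#' @param fundamental A `fundamental_network`; built with
#'   `ws_config(cfg$n_groups, cfg$k, p_ws, seed)` if missing.
#' @param p_ws Rewiring probability used when `fundamental` is missing.
#' @return An object of class `grouped_network`: list with `neurons`,
#'   `synapses`, `fundamental`, `config`.
#' @export
build_network <- function(cfg, fundamental = NULL, p_ws = 0) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(fundamental)) {
    fundamental <- ws_network(ws_config(cfg$n_groups, cfg$k, p_ws,
                                        seed = cfg$seed * 7L + 1L))
  }
  neurons <- withr_seed(cfg$seed * 7L + 2L, build_groups(cfg))
  intra <- withr_seed(cfg$seed * 7L + 3L, wire_intra(neurons, cfg))
  inter <- withr_seed(cfg$seed * 7L + 4L, wire_inter(neurons, fundamental, cfg))
  synapses <- rbind(intra, inter)
  rownames(synapses) <- NULL
  structure(
    list(neurons = neurons, synapses = synapses,
         fundamental = fundamental, config = cfg),
    class = "grouped_network"
  )
}

#' @export
print.grouped_network <- function(x, ...) {
  cat(sprintf(
    "Grouped spiking network: %d groups x %d neurons (%d exc + %d inh), %d synapses (%d intra, %d inter)\n",
    x$config$n_groups, x$config$n_exc + x$config$n_inh,
    x$config$n_exc, x$config$n_inh, nrow(x$synapses),
    sum(x$synapses$kind == "intra"), sum(x$synapses$kind == "inter")
  ))
  invisible(x)
}

#' Export neuron and synapse tables
#'
#' Tab-separated plain-text exports of a `grouped_network`.
#'
#' @param net A `grouped_network`.
#' @param neurons_path,synapses_path Output paths (either may be `NULL`).
#' @export
write_network_tables <- function(net, neurons_path = NULL,
                                 synapses_path = NULL) {
  stopifnot(inherits(net, "grouped_network"))
  if (!is.null(neurons_path)) {
    utils::write.table(net$neurons, neurons_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(synapses_path)) {
    utils::write.table(net$synapses, synapses_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(net)
}
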