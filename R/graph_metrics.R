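#' Group-level synaptic network matrix
#'
#' Aggregates the microscopic interconnections into a directed weighted
#' group graph: entry `(a, b)` is the mean weight of the synapses from
#' neurons of group `a` to neurons of group `b`, exactly zero for pairs
#' without a fundamental edge.
#'
#' @param synapses Synapse table with columns `pre`, `post`, `weight`,
#'   `kind`.
#' @param neurons Neuron table with `id`, `group`.
#' @param n_groups Number of groups.
#' @param weights Optional weight vector overriding `synapses$weight`
#'   (e.g. a post-plasticity snapshot aligned with the table).
#' @return `n_groups` x `n_groups` numeric matrix with zero diagonal.
#' @export
synaptic_matrix <- function(synapses, neurons, n_groups,
                            weights = NULL) {
  if (is.null(weights)) weights <- synapses$weight
  inter <- synapses$kind == "inter"
  ga <- neurons$group[synapses$pre[inter]]
  gb <- neurons$group[synapses$post[inter]]
  w <- weights[inter]
  W <- matrix(0, n_groups, n_groups)
  if (any(inter)) {
    sums <- tapply(w, list(ga, gb), sum)
    counts <- tapply(w, list(ga, gb), length)
    idx <- which(!is.na(sums), arr.ind = TRUE)
    keys <- cbind(as.integer(rownames(sums))[idx[, 1]],
                  as.integer(colnames(sums))[idx[, 2]])
    W[keys] <- sums[idx] / counts[idx]
  }
  W
}

#' Directed weighted clustering coefficient
#'
#' Per-node total clustering of a non-negative directed weighted graph:
#' with weights normalised by the matrix maximum and cube-rooted,
#' `What = (W / max(W))^(1/3)`, the coefficient of node `i` is
#' `[(What + t(What))^3]_ii / (2 * (d_tot * (d_tot - 1) - 2 * d_bi))`,
#' where `d_tot` is the total (in + out) binary degree and `d_bi` the
#' number of reciprocal neighbours. Counts all triangle orientations and
#' lies in `[0, 1]`.
#'
#' @param W Directed weighted adjacency matrix, non-negative, zero
#'   diagonal.
#' @return Numeric vector of per-node coefficients; `NA` where the
#'   denominator vanishes (degree < 2 or all neighbours reciprocal-only
#'   pairs).
#' @export
clustering_directed_weighted <- function(W) {
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  mx <- max(W)
  if (mx == 0) return(rep(NA_real_, nrow(W)))
  What <- (W / mx)^(1 / 3)
  A <- (W > 0) * 1L
  S <- What + t(What)
  num <- diag(S %*% S %*% S)
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- rowSums(A * t(A))
  den <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-node mean shortest path length
#'
#' Breadth-first hop counts on the binarised digraph (an edge wherever the
#' weight exceeds `epsilon`); the per-node mean is taken over reachable
#' targets only, and the number of unreachable targets is reported
#' alongside.
#'
#' @param W Directed weighted adjacency matrix.
#' @param epsilon Weight threshold below or at which an edge is dropped.
#' @return Data frame per node: `node`, `mean_path`, `n_unreachable`.
#'   `mean_path` is `NA` for nodes that reach no other node.
#' @export
shortest_path_lengths <- function(W, epsilon = 0) {
  g <- igraph::graph_from_adjacency_matrix((W > epsilon) * 1,
                                           mode = "directed")
  d <- igraph::distances(g, mode = "out")
  diag(d) <- NA
  reach <- is.finite(d)
  mp <- rowSums(ifelse(reach, d, 0)) / rowSums(reach, na.rm = TRUE)
  mp[rowSums(reach, na.rm = TRUE) == 0] <- NA_real_
  data.frame(
    node = seq_len(nrow(W)),
    mean_path = mp,
    n_unreachable = rowSums(!reach & !is.na(d))
  )
}

#' Degree centrality
#'
#' Number of distinct adjacent groups in the binarised digraph. The default
#' counts a neighbour once whether linked in, out or both, which reduces to
#' the fundamental-network degree when every fundamental edge survives; in-
#' and out-degree variants are available.
#'
#' @param W Directed weighted adjacency matrix.
#' @param mode `"all"` (distinct neighbours), `"in"`, or `"out"`.
#' @param epsilon Weight threshold as in [shortest_path_lengths()].
#' @return Integer vector of per-node degrees.
#' @export
degree_centrality <- function(W, mode = c("all", "in", "out"),
                              epsilon = 0) {
  mode <- match.arg(mode)
  A <- (W > epsilon)
  switch(mode,
    all = as.integer(rowSums(A | t(A))),
    `in` = as.integer(colSums(A)),
    out = as.integer(rowSums(A))
  )
}

#' Per-group mean intraconnection weights by target type
#'
#' Means of the plastic (excitatory-source) intraconnection weights of each
#' group, split by whether the target neuron is excitatory (E to E) or
#' inhibitory (E to I). These are the microscopic quantities whose
#' self-organized balance tracks the complexity of group activity.
#'
#' @param synapses Synapse table (`pre`, `post`, `weight`, `kind`,
#'   `plastic`).
#' @param neurons Neuron table (`id`, `group`, `type`).
#' @param weights Optional weight vector overriding `synapses$weight`.
#' @return Data frame per group: `group`, `w_ee`, `w_ei`.
#' @export
intra_weight_summary <- function(synapses, neurons, weights = NULL) {
  if (is.null(weights)) weights <- synapses$weight
  sel <- synapses$kind == "intra" & synapses$plastic
  g <- neurons$group[synapses$pre[sel]]
  tgt_exc <- neurons$type[synapses$post[sel]] == "exc"
  w <- weights[sel]
  gs <- sort(unique(neurons$group))
  mean_by <- function(mask) {
    m <- tapply(w[mask], factor(g[mask], levels = gs), mean)
    as.numeric(m)
  }
  data.frame(group = gs, w_ee = mean_by(tgt_exc), w_ei = mean_by(!tgt_exc))
}

#' Join structure and dynamics into a per-group metrics table
#'
#' Computes the synaptic-network matrix from a finished simulation and
#' joins the structural measures (clustering, mean path length, degree,
#' intra-weight means) with the dynamical ones (complexity index, firing
#' rates, band peaks) over the analysis window.
#'
#' @param sim A `sim_result` from [run_simulation()].
#' @param mse An [mse_params()] controlling the entropy analysis.
#' @param window Analysis window in ms (default: the schedule's input-free
#'   window).
#' @return A list with `metrics` (data frame, one row per group), `W` (the
#'   synaptic-network matrix) and `mse` (groups x scales sample-entropy
#'   matrix).
#' @export
group_metrics <- function(sim, mse = mse_params(), window = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  net <- sim$network
  cfg <- net$config
  if (is.null(window)) window <- sim$schedule$analysis_window
  W <- synaptic_matrix(net$synapses, net$neurons, cfg$n_groups,
                       weights = sim$weights$final)
  cc <- clustering_directed_weighted(W)
  sp <- shortest_path_lengths(W)
  deg <- degree_centrality(W)
  iw <- intra_weight_summary(net$synapses, net$neurons,
                             weights = sim$weights$final)
  rates <- firing_rates(sim$raster, window, net$neurons)
  lapw <- lap_window(sim$lap, window)
  mse_mat <- mse_matrix(lapw, mse)
  ci <- apply(mse_mat, 1L, function(row)
    if (anyNA(row)) NA_real_ else sum(row))
  peaks <- t(vapply(seq_len(nrow(lapw)), function(g) {
    bp <- band_peaks(amplitude_spectrum(lapw[g, ]))
    c(bp$peak_frequency, bp$peak_amplitude)
  }, numeric(6)))
  metrics <- data.frame(
    group = seq_len(cfg$n_groups),
    clustering = cc,
    mean_path = sp$mean_path,
    degree = deg,
    w_ee = iw$w_ee,
    w_ei = iw$w_ei,
    rate_exc = rates$rate_exc,
    rate_inh = rates$rate_inh,
    complexity = ci,
    peak_f_low = peaks[, 1], peak_f_mid = peaks[, 2],
    peak_f_high = peaks[, 3],
    peak_a_low = peaks[, 4], peak_a_mid = peaks[, 5],
    peak_a_high = peaks[, 6]
  )
  list(metrics = metrics, W = W, mse = mse_mat)
}

#' Write a synaptic-network matrix as CSV
#'
#' @param W Matrix from [synaptic_matrix()].
#' @param path Output file path.
#' @export
write_synaptic_matrix <- function(W, path) {
  utils::write.table(W, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
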