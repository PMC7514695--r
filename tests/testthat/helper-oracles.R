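# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: plain double loops and
# exhaustive enumeration only.

# O(N^2) sample entropy by literal template comparison
oracle_sampen <- function(y, m, r) {
  n <- length(y)
  last_m <- n - m # 1-based: m-template starts are 1..last_m+1
  A <- 0L
  B <- 0L
  for (i in 1:last_m) {
    for (j in (i + 1):(last_m + 1)) {
      if (max(abs(y[i:(i + m - 1)] - y[j:(j + m - 1)])) < r) {
        A <- A + 1L
        if (i <= last_m && j <= last_m && abs(y[i + m] - y[j + m]) < r)
          B <- B + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  cm <- 2 * A / ((last_m + 1) * last_m)
  cm1 <- 2 * B / (last_m * (last_m - 1))
  -log(cm1 / cm)
}

# exhaustive O(N^2) sample entropy via the full pairwise-distance matrix;
# same enumeration as oracle_sampen, fast enough for N = 500 sweeps
oracle_sampen_matrix <- function(y, m, r) {
  n <- length(y)
  D <- abs(outer(y, y, "-")) < r
  lm <- n - m # 1-based m-template starts: 1..lm+1
  match_m <- D[1:(lm + 1), 1:(lm + 1)]
  for (k in 1:(m - 1)) {
    match_m <- match_m & D[(1:(lm + 1)) + k, (1:(lm + 1)) + k]
  }
  A <- (sum(match_m) - (lm + 1)) / 2 # drop self-matches, unordered pairs
  match_m1 <- match_m[1:lm, 1:lm] & D[(1:lm) + m, (1:lm) + m]
  B <- (sum(match_m1) - lm) / 2
  if (A == 0 || B == 0) return(NA_real_)
  cm <- 2 * A / ((lm + 1) * lm)
  cm1 <- 2 * B / (lm * (lm - 1))
  -log(cm1 / cm)
}

# undirected local clustering by exhaustive triangle counting on an
# adjacency matrix; isolated / degree-1 nodes get 0
oracle_undirected_clustering <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] > 0) tri <- tri + 1L
      }
    }
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

# per-node mean shortest path by explicit breadth-first search on a
# directed (or symmetric) 0/1 adjacency matrix; mean over reachable only
oracle_bfs_mean_path <- function(A) {
  n <- nrow(A)
  out <- rep(NA_real_, n)
  for (s in 1:n) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(A[v, ] > 0)) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    reach <- dist[-s]
    reach <- reach[!is.na(reach)]
    if (length(reach) > 0) out[s] <- mean(reach)
  }
  out
}

# directed weighted clustering by exhaustive triad enumeration: for node i,
# sum over ordered neighbour pairs (j, h) of the geometric means of the
# cube-rooted normalised weights along every closed triangle orientation,
# over the number of possible triangles
oracle_dw_clustering <- function(W) {
  n <- nrow(W)
  What <- (W / max(W))^(1 / 3)
  A <- (W > 0) * 1
  out <- rep(NA_real_, n)
  for (i in 1:n) {
    total <- 0
    for (j in 1:n) {
      if (j == i) next
      for (h in 1:n) {
        if (h == i || h == j) next
        # all 8 directed closed triads i-j-h counted via the symmetrised
        # one-third-power weights
        total <- total +
          (What[i, j] + What[j, i]) *
          (What[i, h] + What[h, i]) *
          (What[j, h] + What[h, j])
      }
    }
    d_tot <- sum(A[i, ] > 0) + sum(A[, i] > 0)
    d_bi <- sum(A[i, ] * A[, i])
    den <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
    if (den > 0) out[i] <- total / den
  }
  out
}

# Spearman rho by explicit mid-ranking and the Pearson formula on ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# small random weighted digraph for oracle-equivalence sweeps
random_digraph <- function(n, p = 0.4) {
  W <- matrix(stats::runif(n * n), n, n) *
    (matrix(stats::runif(n * n), n, n) < p)
  diag(W) <- 0
  W
}

# reference forward-Euler Izhikevich integration for a single neuron under
# constant drive, matching the simulator's scheme (two 0.5 ms half-steps
# for v, 1 ms for u, detection at v >= 30, reset v <- c, u <- u + d)
oracle_izhikevich_spikes <- function(a, b, cc, d, v0, u0, current,
                                     t_total_ms) {
  v <- v0
  u <- u0
  spikes <- integer(0)
  # elementary operations written in the simulator's order (v * v, not
  # v^2 = pow) so that agreement is exact, not merely approximate
  for (t in 0:(t_total_ms - 1)) {
    v <- v + 0.5 * (0.04 * v * v + 5 * v + 140 - u + current)
    v <- v + 0.5 * (0.04 * v * v + 5 * v + 140 - u + current)
    u <- u + a * (b * v - u)
    if (v >= 30) {
      spikes <- c(spikes, t)
      v <- cc
      u <- u + d
    }
  }
  spikes
}

# tiny single-population .sim_core invocation used by neuron-level tests:
# n isolated neurons in one group, optional synapse table
run_micro_sim <- function(a, b, cc, d, v0, u0,
                          syn = NULL, t_total_ms = 1000L,
                          tonic_current = 0, t_tonic_ms = t_total_ms,
                          stdp = FALSE, t_stdp_ms = t_total_ms,
                          group = NULL, n_groups = 1L,
                          stdp_par = clustnet::stdp_params(),
                          w_upper = 10) {
  n <- length(a)
  if (is.null(group)) group <- rep(1L, n)
  if (is.null(syn)) {
    syn <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), delay = integer(0),
                      plastic = logical(0))
  }
  clustnet:::.sim_core(
    a, b, cc, d, v0, u0, as.integer(group), rep(TRUE, n),
    as.integer(syn$pre), as.integer(syn$post), as.numeric(syn$weight),
    as.integer(syn$delay), syn$plastic,
    as.integer(n_groups), as.integer(t_total_ms), as.integer(t_tonic_ms),
    as.integer(t_stdp_ms),
    tonic_current, if (tonic_current != 0) 1L else 0L,
    stdp,
    stdp_par$a_plus, stdp_par$a_minus, stdp_par$tau,
    stdp_par$flush_bias, stdp_par$flush_decay, w_upper,
    0L, 0L
  )
}

# compact model for fast end-to-end runs in unit tests (well below the
# smoke preset; dynamics need not be biologically meaningful)
micro_model <- function(seed = 1L, t_total = 4, t_tonic = 3, t_stdp = 2) {
  clustnet::model_config(
    n_groups = 8L, n_exc = 8L, n_inh = 2L, c_intra = 4L, c_inter = 2L,
    k = 4L, t_total = t_total, t_tonic = t_tonic, t_stdp = t_stdp,
    seed = seed
  )
}
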