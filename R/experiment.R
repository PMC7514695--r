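#' Study configuration
#'
#' A sweep over Watts-Strogatz rewiring probabilities with independent
#' replicate simulations per value. The full-scale study uses the sixteen
#' probabilities `{0, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4,
#' 0.5, 0.6, 0.7, 0.8, 0.9, 1}` with ten replicates each.
#'
#' @param p_ws Vector of rewiring probabilities in `[0, 1]`.
#' @param n_sims Replicates per probability (>= 1).
#' @param base A [model_config()] shared by every run.
#' @param mse An [mse_params()] for the complexity analysis.
#' @param seed Base seed; run `(p index i, replicate j)` derives its own
#'   seed deterministically from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(p_ws = c(0, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1,
                                  0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
                         n_sims = 10L, base = model_config(),
                         mse = mse_params(), seed = 1L) {
  if (any(p_ws < 0 | p_ws > 1)) stop("p_ws values must lie in [0, 1]")
  if (n_sims < 1L) stop("n_sims must be >= 1")
  structure(list(p_ws = p_ws, n_sims = as.integer(n_sims), base = base,
                 mse = mse, seed = as.integer(seed)),
            class = "study_config")
}

# deterministic per-run seed, kept well under 2^31
study_run_seed <- function(seed, p_index, sim) {
  (seed * 10007L + p_index * 131L + sim * 7L) %% 1000000L + 1L
}

#' Run one replicate of the study pipeline
#'
#' Topology, network construction, simulation and the structure/dynamics
#' join for a single `(p_ws, replicate)` cell.
#'
#' @param cfg A [study_config()].
#' @param p_ws Rewiring probability for this run.
#' @param run_seed Integer seed for this run.
#' @param stdp Logical; `FALSE` runs the no-plasticity control.
#' @return The [group_metrics()] list, plus `sim` (the `sim_result`).
#' @export
run_single <- function(cfg, p_ws, run_seed, stdp = TRUE) {
  base <- cfg$base
  base$seed <- as.integer(run_seed)
  net <- build_network(base, p_ws = p_ws)
  sched <- sim_schedule(base)
  sim <- run_simulation(net, stdp = stdp,
                        lap_from_ms = sched$t_tonic_ms,
                        spikes_from_ms = sched$t_tonic_ms)
  out <- group_metrics(sim, mse = cfg$mse)
  out$sim <- sim
  out
}

#' Run the full rewiring-probability study
#'
#' For every `p_ws` value and replicate: build the fundamental network and
#' grouped network, simulate the schedule, and join per-group structure
#' (clustering, path length, degree, intra weights) with dynamics
#' (complexity index, firing rates, band peaks). Failures of individual
#' runs are recorded and the sweep continues.
#'
#' @param cfg A [study_config()].
#' @param keep_sims Keep the full `sim_result` objects (memory-heavy).
#' @param verbose Print one line per completed run.
#' @return A list of class `study_results`:
#'   \describe{
#'     \item{table}{long-format data frame `(p_ws, sim, group, ...metrics)`;}
#'     \item{mse_summary}{per `p_ws` and scale: mean and SD of sample
#'       entropy, across groups and replicates and across replicate means;}
#'     \item{seeds}{data frame of the per-run seeds used;}
#'     \item{failures}{list of error messages per failed run.}
#'   }
#' @export
run_study <- function(cfg, keep_sims = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list()
  mse_rows <- list()
  seeds <- list()
  failures <- list()
  sims <- list()
  for (i in seq_along(cfg$p_ws)) {
    for (j in seq_len(cfg$n_sims)) {
      rs <- study_run_seed(cfg$seed, i, j)
      tag <- sprintf("p=%g sim=%d", cfg$p_ws[i], j)
      seeds[[tag]] <- data.frame(p_ws = cfg$p_ws[i], sim = j, seed = rs)
      res <- tryCatch(run_single(cfg, cfg$p_ws[i], rs),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[tag]] <- conditionMessage(res)
        next
      }
      m <- res$metrics
      m <- cbind(data.frame(p_ws = cfg$p_ws[i], sim = j), m)
      rows[[tag]] <- m
      mse_rows[[tag]] <- data.frame(
        p_ws = cfg$p_ws[i], sim = j,
        group = seq_len(nrow(res$mse)),
        scale = rep(cfg$mse$scales, each = nrow(res$mse)),
        sampen = as.vector(res$mse)
      )
      if (keep_sims) sims[[tag]] <- res$sim
      if (verbose) message(tag, " done (seed ", rs, ")")
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  mse_long <- do.call(rbind, mse_rows)
  structure(
    list(table = table, mse_long = mse_long,
         mse_summary = summarize_mse(mse_long),
         seeds = do.call(rbind, seeds), failures = failures,
         sims = if (keep_sims) sims else NULL,
         config = cfg),
    class = "study_results"
  )
}

# per (p_ws, scale): mean/SD across all groups x sims, and across the
# per-replicate group means
summarize_mse <- function(mse_long) {
  if (is.null(mse_long) || nrow(mse_long) == 0L) return(NULL)
  mn <- stats::aggregate(sampen ~ p_ws + scale, data = mse_long,
                         FUN = mean, na.action = stats::na.omit)
  sg <- stats::aggregate(sampen ~ p_ws + scale, data = mse_long,
                         FUN = stats::sd, na.action = stats::na.omit)
  sim_means <- stats::aggregate(sampen ~ p_ws + scale + sim,
                                data = mse_long, FUN = mean,
                                na.action = stats::na.omit)
  ss <- stats::aggregate(sampen ~ p_ws + scale, data = sim_means,
                         FUN = stats::sd)
  key <- function(df) paste(df$p_ws, df$scale)
  out <- data.frame(p_ws = mn$p_ws, scale = mn$scale, mean = mn$sampen)
  out$sd_groups <- sg$sampen[match(key(out), key(sg))]
  out$sd_sims <- ss$sampen[match(key(out), key(ss))]
  out[order(out$p_ws, out$scale), ]
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf(
    "Study: %d p_ws values x %d replicates, %d group rows, %d failures\n",
    length(x$config$p_ws), x$config$n_sims,
    if (is.null(x$table)) 0L else nrow(x$table), length(x$failures)
  ))
  invisible(x)
}

#' Lowest- and highest-complexity groups of a run
#'
#' @param complexity Numeric complexity index per group.
#' @param n How many groups per extreme (default 10).
#' @return List with integer group-id vectors `low` and `high`; ties break
#'   by group id, and the two sets are disjoint.
#' @export
select_extreme_groups <- function(complexity, n = 10L) {
  ng <- length(complexity)
  if (n > ng %/% 2L) stop("n must not exceed half the number of groups")
  ord <- order(complexity, seq_len(ng)) # stable: ties by group id
  list(low = sort(ord[seq_len(n)]),
       high = sort(ord[(ng - n + 1L):ng]))
}

#' Spearman correlations between structure and dynamics
#'
#' Rank correlations between each structural column (clustering, degree,
#' mean path, E-to-E and E-to-I intra weights) and each dynamical column
#' (complexity index, excitatory and inhibitory firing rates), per `p_ws`
#' and pooled over the whole table. The underlying study reports these
#' relationships graphically; the correlation is this package's
#' quantitative summary of the same scatter.
#'
#' @param table Long-format results table from [run_study()] (or any data
#'   frame with the named columns).
#' @param per_p Also return per-`p_ws` correlations.
#' @return Data frame: `p_ws` (`NA` = pooled), `structure`, `dynamic`,
#'   `rho`, `n`. Constant columns yield `NA` with a warning suppressed.
#' @export
correlate_structure_dynamics <- function(table, per_p = TRUE) {
  struct_cols <- c("clustering", "degree", "mean_path", "w_ee", "w_ei")
  dyn_cols <- c("complexity", "rate_exc", "rate_inh")
  one_block <- function(df, p_label) {
    out <- expand.grid(structure = struct_cols, dynamic = dyn_cols,
                       stringsAsFactors = FALSE)
    out$p_ws <- p_label
    out$rho <- NA_real_
    out$n <- NA_integer_
    for (r in seq_len(nrow(out))) {
      x <- df[[out$structure[r]]]
      y <- df[[out$dynamic[r]]]
      ok <- is.finite(x) & is.finite(y)
      out$n[r] <- sum(ok)
      if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        out$rho[r] <- suppressWarnings(
          stats::cor(x[ok], y[ok], method = "spearman"))
      }
    }
    out[, c("p_ws", "structure", "dynamic", "rho", "n")]
  }
  blocks <- list(one_block(table, NA_real_))
  if (per_p) {
    for (p in sort(unique(table$p_ws))) {
      blocks[[length(blocks) + 1L]] <-
        one_block(table[table$p_ws == p, , drop = FALSE], p)
    }
  }
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}

#' Write study results to plain-text files
#'
#' @param results A `study_results`.
#' @param dir Output directory (created if missing).
#' @export
write_study <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$table, file.path(dir, "group_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$mse_summary, file.path(dir, "mse_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(results$seeds, file.path(dir, "seeds.csv"),
                   row.names = FALSE)
  invisible(dir)
}
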