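#' Watts-Strogatz configuration for the fundamental network
#'
#' The fundamental network is the fixed macroscopic graph on neuron groups:
#' which group pairs are allowed to exchange interconnections. It is built by
#' the classic Watts-Strogatz procedure (ring lattice plus probabilistic
#' rewiring), which tunes clustering coefficient and path length without
#' changing the number of edges.
#'
#' @param n_groups Number of nodes (neuron groups).
#' @param k Even number of lattice neighbours per node; must satisfy
#'   `k < n_groups`.
#' @param p_ws Rewiring probability in `[0, 1]`.
#' @param seed Integer seed used when the network is built.
#' @return An object of class `ws_config`.
#' @export
ws_config <- function(n_groups, k = 6L, p_ws = 0, seed = 1L) {
  n_groups <- as.integer(n_groups)
  k <- as.integer(k)
  if (n_groups < 3L) stop("n_groups must be at least 3")
  if (k <= 0L || k %% 2L != 0L) stop("k must be a positive even integer")
  if (k >= n_groups) stop("k must be smaller than n_groups")
  if (p_ws < 0 || p_ws > 1) stop("p_ws must lie in [0, 1]")
  structure(
    list(n_groups = n_groups, k = k, p_ws = p_ws, seed = as.integer(seed)),
    class = "ws_config"
  )
}

new_fundamental_network <- function(n_groups, edges) {
  # edges: 2-column integer matrix, 1-based node ids, each row i < j
  structure(
    list(n_groups = as.integer(n_groups), edges = edges),
    class = "fundamental_network"
  )
}

#' @export
print.fundamental_network <- function(x, ...) {
  cat(sprintf(
    "Fundamental network: %d groups, %d undirected edges\n",
    x$n_groups, nrow(x$edges)
  ))
  invisible(x)
}

canonical_edges <- function(edges) {
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) {
    tmp <- edges[swap, 1L]
    edges[swap, 1L] <- edges[swap, 2L]
    edges[swap, 2L] <- tmp
  }
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' Ring lattice on neuron groups
#'
#' Connects node `i` to its `k/2` neighbours on each side of a ring, giving
#' every node degree exactly `k` and `n_groups * k / 2` edges in total.
#'
#' @param cfg A [ws_config()].
#' @return A `fundamental_network`.
#' @export
build_ring_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "ws_config"))
  n <- cfg$n_groups
  half <- cfg$k %/% 2L
  from <- rep(seq_len(n), each = half)
  off <- rep(seq_len(half), times = n)
  to <- ((from - 1L + off) %% n) + 1L
  edges <- canonical_edges(cbind(from, to, deparse.level = 0))
  new_fundamental_network(n, edges)
}

#' Rewire lattice edges with probability `p_ws`
#'
#' Each edge is independently selected with probability `p_ws`; a selected
#' edge keeps its first endpoint (the anchor) and moves the other endpoint to
#' a uniformly chosen node, redrawing on self-loops and duplicates. The edge
#' count is therefore conserved for every `p_ws` and the graph stays simple.
#'
#' Uses the R random-number stream; call `set.seed()` (or use
#' [ws_network()], which seeds itself) for reproducibility.
#'
#' @param net A `fundamental_network`.
#' @param p_ws Rewiring probability.
#' @return A `fundamental_network` with the same node and edge counts.
#' @export
rewire_edges <- function(net, p_ws) {
  stopifnot(inherits(net, "fundamental_network"))
  if (p_ws < 0 || p_ws > 1) stop("p_ws must lie in [0, 1]")
  n <- net$n_groups
  edges <- net$edges
  m <- nrow(edges)
  # adjacency hash: key a*n + b for a < b
  key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1) * n + hi
  }
  present <- new.env(hash = TRUE, size = 2L * m)
  for (e in seq_len(m)) {
    assign(as.character(key(edges[e, 1L], edges[e, 2L])), TRUE,
           envir = present)
  }
  pick <- stats::runif(m) < p_ws
  for (e in seq_len(m)) {
    if (!pick[e]) next
    a <- edges[e, 1L]
    b <- edges[e, 2L]
    # try new endpoints until simple; a full node has no legal target
    if (sum(vapply(seq_len(n), function(x) {
      x != a && exists(as.character(key(a, x)), envir = present)
    }, logical(1))) >= n - 1L) next
    rm(list = as.character(key(a, b)), envir = present)
    repeat {
      cand <- sample.int(n, 1L)
      if (cand == a) next
      if (exists(as.character(key(a, cand)), envir = present)) next
      edges[e, 2L] <- cand
      edges[e, 1L] <- a
      assign(as.character(key(a, cand)), TRUE, envir = present)
      break
    }
  }
  new_fundamental_network(n, canonical_edges(edges))
}

#' Build a Watts-Strogatz fundamental network
#'
#' Composition of [build_ring_lattice()] and [rewire_edges()], deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [ws_config()].
#' @return A `fundamental_network`.
#' @export
ws_network <- function(cfg) {
  stopifnot(inherits(cfg, "ws_config"))
  lattice <- build_ring_lattice(cfg)
  if (cfg$p_ws == 0) return(lattice)
  withr_seed(cfg$seed, rewire_edges(lattice, cfg$p_ws))
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Adjacency matrix of a fundamental network
#'
#' @param net A `fundamental_network`.
#' @return A symmetric 0/1 integer matrix with zero diagonal.
#' @export
fn_adjacency <- function(net) {
  stopifnot(inherits(net, "fundamental_network"))
  A <- matrix(0L, net$n_groups, net$n_groups)
  A[net$edges] <- 1L
  A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1L
  A
}

#' Convert a fundamental network to igraph
#'
#' @param net A `fundamental_network`.
#' @return An undirected `igraph` graph.
#' @export
fn_as_igraph <- function(net) {
  stopifnot(inherits(net, "fundamental_network"))
  igraph::graph_from_edgelist(net$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, net$n_groups - max(net$edges)))
}

#' Structural summary of an undirected group graph
#'
#' Mean local clustering coefficient (triangle definition, nodes of degree
#' < 2 counted as 0) and mean shortest path length over reachable ordered
#' pairs, computed with igraph.
#'
#' @param net A `fundamental_network`.
#' @return A list with `mean_clustering`, `mean_path_length`, `degrees`.
#' @export
fn_summary <- function(net) {
  g <- fn_as_igraph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  d <- igraph::distances(g)
  finite <- is.finite(d) & d > 0
  list(
    mean_clustering = mean(cc),
    mean_path_length = mean(d[finite]),
    degrees = igraph::degree(g)
  )
}

#' Write a fundamental network as a two-column edge list
#'
#' Tab-separated, 1-based node ids, one undirected edge per row.
#'
#' @param net A `fundamental_network`.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "fundamental_network"))
  utils::write.table(net$edges, path, sep = "\t",
                     row.names = FALSE, col.names = c("from", "to"),
                     quote = FALSE)
  invisible(path)
}

#' Export a fundamental network as GraphML
#'
#' @param net A `fundamental_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(fn_as_igraph(net), path, format = "graphml")
  invisible(path)
}
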