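test_that("synaptic matrix averages interconnection weights per pair", {
  neurons <- data.frame(id = 1:6, group = rep(1:2, each = 3),
                        type = rep("exc", 6))
  syn <- data.frame(
    pre = c(1L, 2L, 3L, 4L, 1L),
    post = c(4L, 5L, 6L, 1L, 2L),
    weight = c(6, 6, 6, 2, 99),
    kind = c("inter", "inter", "inter", "inter", "intra"),
    plastic = TRUE
  )
  W <- synaptic_matrix(syn, neurons, 2L)
  expect_equal(W[1, 2], 6)
  expect_equal(W[2, 1], 2)
  expect_equal(diag(W), c(0, 0))
})

test_that("directed weighted clustering hits the analytic toy values", {
  expect_equal(
    clustering_directed_weighted(toy_connectivity("reciprocal_triangle")),
    rep(1, 3)
  )
  expect_equal(
    clustering_directed_weighted(toy_connectivity("directed_cycle_3")),
    rep(0.5, 3)
  )
  # pure cycle of length 10 has no triangles at all
  expect_equal(
    clustering_directed_weighted(toy_connectivity("directed_cycle_10")),
    rep(0, 10)
  )
  expect_error(clustering_directed_weighted(matrix(c(0, -1, 1, 0), 2)),
               "non-negative")
})

test_that("clustering matches exhaustive triad enumeration on random digraphs", {
  set.seed(12)
  for (rep in 1:30) {
    W <- random_digraph(sample(4:8, 1))
    if (max(W) == 0) next
    expect_equal(clustering_directed_weighted(W), oracle_dw_clustering(W),
                 tolerance = 1e-12)
  }
})

test_that("clustering lies in [0,1] and flags degree-deficient nodes", {
  set.seed(13)
  for (rep in 1:20) {
    W <- random_digraph(6, p = 0.5)
    if (max(W) == 0) next
    cc <- clustering_directed_weighted(W)
    ok <- !is.na(cc)
    expect_true(all(cc[ok] >= 0 & cc[ok] <= 1 + 1e-12))
  }
  # a single reciprocal pair: both nodes have d_tot = 2, d_bi = 1 -> NA
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  cc <- clustering_directed_weighted(W)
  expect_true(all(is.na(cc[1:2])))
})

test_that("mean shortest paths follow BFS hop counts", {
  full <- matrix(1, 4, 4) - diag(4)
  expect_equal(shortest_path_lengths(full)$mean_path, rep(1, 4))
  # 10-node one-way ring: hop counts 1..9 from every node, mean 5
  cyc10 <- toy_connectivity("directed_cycle_10")
  expect_equal(shortest_path_lengths(cyc10)$mean_path, rep(mean(1:9), 10))

  set.seed(14)
  for (rep in 1:30) {
    W <- random_digraph(sample(4:8, 1), p = 0.5)
    got <- shortest_path_lengths(W)$mean_path
    want <- oracle_bfs_mean_path((W > 0) * 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # isolated node is flagged NA, not fatal
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1
  sp <- shortest_path_lengths(W)
  expect_true(is.na(sp$mean_path[3]))
  expect_equal(sp$n_unreachable[1], 1L) # node 1 cannot reach node 3
})

test_that("degree centrality counts distinct neighbours", {
  lat <- build_ring_lattice(ws_config(20, 6))
  Wl <- fn_adjacency(lat) * 6.0
  expect_equal(degree_centrality(Wl), rep(6L, 20))
  star <- toy_connectivity("star_8")
  expect_equal(degree_centrality(star)[1], 7L)
  expect_equal(degree_centrality(star)[-1], rep(1L, 7))
  # in/out variants on an asymmetric graph
  cyc <- toy_connectivity("directed_cycle_3")
  expect_equal(degree_centrality(cyc, "in"), rep(1L, 3))
  expect_equal(degree_centrality(cyc, "out"), rep(1L, 3))
  expect_equal(degree_centrality(cyc, "all"), rep(2L, 3))
})

test_that("degree variance grows with rewiring while the mean is fixed", {
  vars <- sapply(1:20, function(s) {
    d0 <- degree_centrality(fn_adjacency(
      ws_network(ws_config(50, 6, 0, seed = s))) * 1.0)
    d1 <- degree_centrality(fn_adjacency(
      ws_network(ws_config(50, 6, 1, seed = s))) * 1.0)
    c(var(d0), var(d1))
  })
  expect_equal(mean(vars[1, ]), 0)
  expect_gt(mean(vars[2, ]), 0.5)
})

test_that("intra weight summaries split by target type", {
  neurons <- data.frame(id = 1:4, group = rep(1L, 4),
                        type = c("exc", "exc", "inh", "inh"))
  syn <- data.frame(
    pre = c(1L, 1L, 2L, 2L, 3L),
    post = c(2L, 3L, 1L, 4L, 1L),
    weight = c(4, 8, 6, 2, -5),
    kind = "intra",
    plastic = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  iw <- intra_weight_summary(syn, neurons)
  expect_equal(iw$w_ee, mean(c(4, 6)))
  expect_equal(iw$w_ei, mean(c(8, 2)))
  # before plasticity every plastic mean equals the initial weight
  cfg <- micro_model(seed = 2L)
  net <- build_network(cfg, p_ws = 0)
  iw0 <- intra_weight_summary(net$synapses, net$neurons)
  expect_true(all(iw0$w_ee == cfg$w_init_exc))
  expect_true(all(iw0$w_ei == cfg$w_init_exc))
})

test_that("graph metrics are equivariant under group relabeling", {
  set.seed(15)
  W <- random_digraph(7, p = 0.5)
  perm <- sample(7)
  Wp <- W[perm, perm]
  expect_equal(clustering_directed_weighted(W)[perm],
               clustering_directed_weighted(Wp))
  expect_equal(shortest_path_lengths(W)$mean_path[perm],
               shortest_path_lengths(Wp)$mean_path)
  expect_equal(degree_centrality(W)[perm], degree_centrality(Wp))
})
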