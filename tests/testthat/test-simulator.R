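test_that("a resting regular-spiking neuron stays silent", {
  res <- run_micro_sim(a = 0.02, b = 0.2, cc = -65, d = 8,
                       v0 = -65, u0 = -13, t_total_ms = 1000L)
  expect_equal(length(res$spike_t), 0L)
  # the membrane relaxes toward the stable fixed point near -70 mV and
  # never approaches threshold
  expect_true(all(res$lap[1, ] < -49))
  expect_true(all(res$lap[1, ] > -80))
})

test_that("constant-drive spike times match an independent integration", {
  for (current in c(6, 10, 15)) {
    res <- run_micro_sim(a = 0.02, b = 0.2, cc = -65, d = 8,
                         v0 = -65, u0 = -13, t_total_ms = 1000L,
                         tonic_current = current)
    oracle <- oracle_izhikevich_spikes(0.02, 0.2, -65, 8, -65, -13,
                                       current, 1000L)
    expect_gt(length(oracle), 3)
    expect_identical(res$spike_t, as.integer(oracle))
  }
})

test_that("synaptic deliveries respect the transmission delay", {
  # neuron 1 (group 1) fires immediately; a strong synapse with delay 7
  # must not move neuron 2 (group 2) before t + 7
  syn <- data.frame(pre = 1L, post = 2L, weight = 100, delay = 7L,
                    plastic = FALSE)
  res <- run_micro_sim(a = rep(0.02, 2), b = rep(0.2, 2),
                       cc = rep(-65, 2), d = rep(8, 2),
                       v0 = c(35, -65), u0 = c(-13, -13),
                       syn = syn, t_total_ms = 50L,
                       group = c(1L, 2L), n_groups = 2L)
  t1 <- res$spike_t[res$spike_id == 1][1]
  t2 <- res$spike_t[res$spike_id == 2][1]
  expect_identical(t1, 0L)
  expect_gte(t2, t1 + 7L)
  expect_lte(t2, t1 + 8L) # the 100-unit kick fires it on arrival
})

test_that("isolated pre-before-post pairing potentiates exactly once", {
  # A fires at t = 0; its spike arrives at B at t = 5 and makes B fire;
  # the single flush then applies bias + a_plus * exp(-dt / tau)
  par <- stdp_params()
  syn <- data.frame(pre = 1L, post = 2L, weight = 30, delay = 5L,
                    plastic = TRUE)
  res <- run_micro_sim(a = rep(0.02, 2), b = rep(0.2, 2),
                       cc = rep(-65, 2), d = rep(8, 2),
                       v0 = c(35, -65), u0 = c(-13, -13),
                       syn = syn, t_total_ms = 1000L,
                       stdp = TRUE, stdp_par = par,
                       group = c(1L, 2L), n_groups = 2L, w_upper = 50)
  t_b <- res$spike_t[res$spike_id == 2][1]
  expect_false(is.na(t_b))
  dt <- t_b - 5L # post fire minus arrival
  expect_gte(dt, 0L)
  expected <- 30 + par$flush_bias + par$a_plus * exp(-dt / par$tau)
  expect_equal(res$weights_final[1], expected, tolerance = 1e-12)
})

test_that("isolated post-before-pre pairing depresses exactly once", {
  # both neurons fire at t = 0; A's spike reaches B at t = 5, i.e. 5 ms
  # after B's spike -> depression a_minus * exp(-5 / tau); the weak weight
  # (0.5) cannot re-excite B, so the pairing stays isolated
  par <- stdp_params()
  syn <- data.frame(pre = 1L, post = 2L, weight = 0.5, delay = 5L,
                    plastic = TRUE)
  res <- run_micro_sim(a = rep(0.02, 2), b = rep(0.2, 2),
                       cc = rep(-65, 2), d = rep(8, 2),
                       v0 = c(35, 35), u0 = c(-13, -13),
                       syn = syn, t_total_ms = 1000L,
                       stdp = TRUE, stdp_par = par,
                       group = c(1L, 2L), n_groups = 2L, w_upper = 10)
  expect_identical(res$spike_t[res$spike_id == 2], 0L)
  expected <- 0.5 + par$flush_bias - par$a_minus * exp(-5 / par$tau)
  expect_equal(res$weights_final[1], expected, tolerance = 1e-12)
})

test_that("end-to-end micro run is deterministic and respects bounds", {
  cfg <- micro_model(seed = 4L)
  net <- build_network(cfg, p_ws = 0.2)
  s1 <- run_simulation(net)
  s2 <- run_simulation(net)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$weights$final, s2$weights$final)
  expect_identical(unclass(s1$lap), unclass(s2$lap))

  plast <- net$synapses$plastic
  expect_true(all(s1$weights$post_stdp[plast] >= 0))
  expect_true(all(s1$weights$post_stdp[plast] <= cfg$w_upper))
  expect_true(all(s1$weights$final[plast] >= 0))
  expect_true(all(s1$weights$final[plast] <= cfg$w_upper))
  # inhibitory weights bit-identical through the run
  expect_identical(s1$weights$final[!plast], net$synapses$weight[!plast])
  expect_identical(s1$weights$post_stdp[!plast],
                   net$synapses$weight[!plast])
})

test_that("different input seeds decouple from the frozen wiring", {
  cfg <- micro_model(seed = 4L)
  net <- build_network(cfg, p_ws = 0.2)
  s1 <- run_simulation(net, seed = 101L)
  s2 <- run_simulation(net, seed = 102L)
  expect_false(identical(s1$raster, s2$raster))
})

test_that("lap windowing slices absolute run time", {
  cfg <- micro_model(seed = 6L)
  net <- build_network(cfg, p_ws = 0)
  sim <- run_simulation(net, lap_from_ms = 1000L)
  expect_equal(ncol(sim$lap), sim$schedule$t_total_ms - 1000L)
  w <- lap_window(sim$lap, c(2000L, 2500L))
  expect_equal(dim(w), c(cfg$n_groups, 500L))
  expect_equal(w[, 1], unclass(sim$lap)[, 1001L])
  expect_error(lap_window(sim$lap, c(0L, 500L)), "window")
})
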