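cfg_small <- clustnet::model_config(
  n_groups = 4L, n_exc = 12L, n_inh = 3L, c_intra = 5L, c_inter = 2L,
  k = 2L, t_total = 2, t_tonic = 2, t_stdp = 1, seed = 9L
)

test_that("build_groups lays out populations with the reference parameters", {
  set.seed(1)
  nr <- build_groups(cfg_small)
  expect_equal(nrow(nr), 4L * 15L)
  expect_equal(sum(nr$type == "exc"), 48L)
  expect_equal(as.vector(table(nr$group)), rep(15L, 4))
  expect_true(all(nr$v0 == -65))
  expect_equal(nr$u0, nr$b * -65)

  exc <- nr[nr$type == "exc", ]
  inh <- nr[nr$type == "inh", ]
  # heterogeneity ties c and d to the same per-neuron draw:
  # c = -65 + 15 r^2, d = 8 - 6 r^2  =>  d = 8 - 6 (c + 65) / 15
  expect_equal(exc$d, 8 - 6 * (exc$c + 65) / 15)
  expect_true(all(exc$a == 0.02 & exc$b == 0.2))
  expect_true(all(exc$c >= -65 & exc$c <= -50 & exc$d >= 2 & exc$d <= 8))
  # inhibitory: a = 0.02 + 0.08 r, b = 0.25 - 0.05 r share one draw
  expect_equal(inh$b, 0.25 - 0.05 * (inh$a - 0.02) / 0.08)
  expect_true(all(inh$c == -65 & inh$d == 2))
})

test_that("intra wiring satisfies the fan-out and target-type rules", {
  set.seed(2)
  nr <- build_groups(cfg_small)
  syn <- wire_intra(nr, cfg_small)
  expect_equal(nrow(syn), nrow(nr) * cfg_small$c_intra)
  expect_true(all(table(syn$pre) == cfg_small$c_intra))
  expect_true(all(syn$pre != syn$post))
  # targets stay within the source group
  expect_true(all(nr$group[syn$pre] == nr$group[syn$post]))
  # per-source targets are distinct
  expect_equal(anyDuplicated(syn[, c("pre", "post")]), 0L)
  # inhibitory neurons project to excitatory neurons only
  inh_src <- nr$type[syn$pre] == "inh"
  expect_true(all(nr$type[syn$post[inh_src]] == "exc"))
  # weights, delays, plasticity by source type
  expect_true(all(syn$weight[!inh_src] == cfg_small$w_init_exc))
  expect_true(all(syn$weight[inh_src] == cfg_small$w_init_inh))
  expect_true(all(syn$plastic == !inh_src))
  expect_true(all(syn$delay[inh_src] == cfg_small$delay_intra_inh))
  expect_true(all(syn$delay[!inh_src] >= cfg_small$delay_intra_exc[1] &
                    syn$delay[!inh_src] <= cfg_small$delay_intra_exc[2]))
})

test_that("inter wiring follows the fundamental network", {
  set.seed(3)
  nr <- build_groups(cfg_small)
  fn <- build_ring_lattice(ws_config(4, 2)) # 4-cycle
  syn <- wire_inter(nr, fn, cfg_small)
  # every excitatory neuron has c_inter targets per adjacent group
  expect_equal(nrow(syn), 2L * nrow(fn$edges) * 12L * cfg_small$c_inter)
  deg <- 2L # each group has two neighbours in the 4-cycle
  exc_ids <- nr$id[nr$type == "exc"]
  expect_true(all(table(factor(syn$pre, levels = exc_ids)) ==
                    deg * cfg_small$c_inter))
  # inhibitory neurons have no interconnections
  expect_false(any(nr$type[syn$pre] == "inh"))
  # group pairs without a fundamental edge have no synapses: in the
  # 4-cycle, 1-3 and 2-4 are unlinked
  gpair <- paste(nr$group[syn$pre], nr$group[syn$post])
  expect_false(any(gpair %in% c("1 3", "3 1", "2 4", "4 2")))
  expect_true(all(syn$plastic))
  expect_true(all(syn$delay >= cfg_small$delay_inter_exc[1] &
                    syn$delay <= cfg_small$delay_inter_exc[2]))
})

test_that("build_network composes deterministically", {
  net1 <- build_network(cfg_small, p_ws = 0.5)
  net2 <- build_network(cfg_small, p_ws = 0.5)
  expect_identical(net1$synapses, net2$synapses)
  expect_identical(net1$neurons, net2$neurons)
  expect_identical(net1$fundamental$edges, net2$fundamental$edges)

  # synapse-count identities
  n <- nrow(net1$neurons)
  n_edges <- nrow(net1$fundamental$edges)
  expect_equal(sum(net1$synapses$kind == "intra"), n * cfg_small$c_intra)
  expect_equal(sum(net1$synapses$kind == "inter"),
               2L * n_edges * 12L * cfg_small$c_inter)
  # sign segregation: plastic <=> excitatory source
  w <- net1$synapses$weight
  expect_true(all(w[net1$synapses$plastic] > 0))
  expect_true(all(w[!net1$synapses$plastic] == cfg_small$w_init_inh))
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(w_init_inh = 5), "negative")
  expect_error(model_config(w_init_exc = 20, w_upper = 10), "exceed")
  expect_error(model_config(t_stdp = 1300), "schedule")
  expect_error(model_config(n_exc = 50, n_inh = 10, c_intra = 60),
               "c_intra")
})
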