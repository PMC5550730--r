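test_that("synapse table carries the printed conductances, reversals and signs", {
  sp <- synapse_params()
  row <- function(pre, post) sp[sp$pre == pre & sp$post == post, ]
  expect_equal(row("GPi", "TH")[, c("g", "E")], data.frame(g = 0.17, E = -85),
               ignore_attr = TRUE)
  expect_equal(row("GPe", "STN")$g, 0.5)
  expect_equal(row("STN", "GPe")$g, 0.15)
  expect_equal(row("GPe", "GPe")$g, 0.5)
  expect_equal(row("STN", "GPi")$g, 0.15)
  expect_equal(row("GPe", "GPi")$g, 0.5)
  # sign convention is tied to the reversal potential
  expect_true(all((sp$sign == "excitatory") == (sp$E == 0)))
  expect_true(all((sp$sign == "inhibitory") == (sp$E == -85)))
})

test_that("topology satisfies the printed fan-in for every postsynaptic neuron", {
  for (mode in c("structured", "random")) {
    topo <- build_topology(50, seed = 7, mode = mode)
    expect_equal(dim(topo$gpe2stn), c(50, 2))  # each STN <- 2 GPe
    expect_equal(dim(topo$stn2gpe), c(50, 2))  # each GPe <- 2 STN
    expect_equal(dim(topo$gpe2gpe), c(50, 2))  # each GPe <- 2 GPe
    expect_equal(dim(topo$stn2gpi), c(50, 2))  # each GPi <- 2 STN
    expect_equal(dim(topo$gpe2gpi), c(50, 2))  # each GPi <- 2 GPe
    expect_equal(dim(topo$gpi2th), c(50, 1))   # each TH <- 1 GPi
    # two distinct partners everywhere, and no GPe self-inhibition
    for (nm in c("gpe2stn", "stn2gpe", "gpe2gpe", "stn2gpi", "gpe2gpi")) {
      expect_true(all(topo[[nm]][, 1] != topo[[nm]][, 2]))
    }
    expect_true(all(topo$gpe2gpe != seq_len(50)))
    # wiring conservation: total edges = n * (2*5 + 1)
    expect_equal(bgdbs:::topology_edge_count(topo), 50 * 11)
  }
})

test_that("structured wiring is the unique wrap-around assignment and deterministic", {
  t1 <- build_topology(3, seed = 1, mode = "structured")
  t2 <- build_topology(3, seed = 99, mode = "structured")
  expect_identical(t1$stn2gpe, t2$stn2gpe)
  expect_equal(t1$stn2gpe, cbind(1:3, c(2L, 3L, 1L)))
  expect_error(build_topology(2), "n_per_pop")
})

test_that("random wiring differs across seeds but not within a seed", {
  a <- build_topology(100, seed = 1, mode = "random")
  b <- build_topology(100, seed = 1, mode = "random")
  c <- build_topology(100, seed = 2, mode = "random")
  expect_identical(a$gpe2stn, b$gpe2stn)
  expect_false(identical(a$gpe2stn, c$gpe2stn))
})

test_that("synaptic current follows g*sum(s)*(V - E) with fan-in checks", {
  sp <- synapse_params()
  gpi2th <- sp[sp$pre == "GPi" & sp$post == "TH", ]
  expect_equal(synaptic_current(gpi2th, s_values = 0, V_post = -60), 0)
  expect_equal(synaptic_current(gpi2th, s_values = 1, V_post = -85), 0)  # reversal
  expect_equal(synaptic_current(gpi2th, s_values = 1, V_post = -60),
               0.17 * (-60 + 85))  # 4.25 uA/cm^2
  gpe2stn <- sp[sp$pre == "GPe" & sp$post == "STN", ]
  expect_error(synaptic_current(gpe2stn, s_values = 1, V_post = -60), "wiring")
})

test_that("afferent currents depolarize or hyperpolarize according to their reversal", {
  sp <- synapse_params()
  V <- -60  # between E_inh = -85 and E_exc = 0
  exc <- sp[sp$pre == "STN" & sp$post == "GPe", ]
  inh <- sp[sp$pre == "GPe" & sp$post == "STN", ]
  # currents enter dV/dt with a leading minus
  expect_gt(-synaptic_current(exc, c(0.5, 0.5), V), 0)
  expect_lt(-synaptic_current(inh, c(0.5, 0.5), V), 0)
})

test_that("synaptic gate kinetics rise under presynaptic spiking and decay after", {
  # subthreshold presynaptic voltage: s stays at 0
  s <- 0
  for (i in 1:100) s <- update_synapse(s, V_pre = -60, dt = 0.1, "excitatory")
  expect_lt(s, 1e-6)
  # clamped above threshold: s approaches its saturation within 1e-3
  kin <- cell_params()$synapses$kinetics$excitatory
  H <- 1 / (1 + exp(-(0 + 20) / 2))
  s_sat <- kin$alpha * H / (kin$alpha * H + kin$beta)
  rise_tau <- 1 / (kin$alpha * H + kin$beta)
  s <- 0
  steps <- ceiling(10 * rise_tau / 0.01)
  for (i in seq_len(steps)) s <- update_synapse(s, V_pre = 0, dt = 0.01, "excitatory")
  expect_equal(s, s_sat, tolerance = 1e-3)
  # after a 1 ms spike, inhibitory s decays below 0.05 within 5 decay constants
  kin_i <- cell_params()$synapses$kinetics$inhibitory
  s <- update_synapse(0, V_pre = 0, dt = 1, "inhibitory")
  decay_tau <- 1 / kin_i$beta
  for (i in seq_len(ceiling(5 * decay_tau / 0.1))) {
    s <- update_synapse(s, V_pre = -70, dt = 0.1, "inhibitory")
  }
  expect_lt(s, 0.05)
})

test_that("topology round-trips through JSON exactly", {
  topo <- build_topology(20, seed = 3, mode = "random")
  f <- tempfile(fileext = ".json")
  topology_to_json(topo, f)
  back <- topology_from_json(f)
  for (nm in c("gpi2th", "gpe2stn", "stn2gpe", "gpe2gpe", "stn2gpi", "gpe2gpi")) {
    expect_equal(unname(topo[[nm]]), unname(back[[nm]]))
  }
  expect_identical(back$mode, "random")
  unlink(f)
})
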