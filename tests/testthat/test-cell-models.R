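test_that("ionic current vanishes at the reversal potential for every channel", {
  for (ct in c("TH", "STN", "GPe", "GPi")) {
    for (ch in cell_params(ct)$channels) {
      for (gates in list(c(1, 1), c(0.5, 0.2), c(0, 1))) {
        expect_identical(ionic_current(ch, V = ch$E, m = gates[1], h = gates[2]), 0)
      }
    }
  }
})

test_that("ionic current reproduces direct arithmetic and closed-gate nulls", {
  # TH leak: g = 0.05 mS/cm^2, E = -70 mV, ungated, at V = -60 -> 0.5 uA/cm^2
  expect_equal(ionic_current(cell_params("TH")$channels$L, V = -60), 0.5)
  # a closed activation gate silences any channel with M >= 1
  na <- cell_params("STN")$channels$Na
  expect_identical(ionic_current(na, V = 0, m = 0, h = 1), 0)
})

test_that("gating curves are bounded and time constants positive over the physiological range", {
  V <- seq(-120, 60, by = 1)
  for (ct in c("TH", "STN", "GPe", "GPi")) {
    kin <- gating_kinetics(ct)
    for (g in kin) {
      x <- if (identical(g$mode, "instantaneous_of_r")) {
        g$steady_state(seq(0, 1, by = 0.05))
      } else {
        g$steady_state(V)
      }
      expect_true(all(x >= 0 & x <= 1))
      if (identical(g$mode, "dynamic")) {
        expect_true(all(g$time_constant(V) > 0))
      }
    }
  }
})

test_that("gate_derivative implements linear relaxation and rejects instantaneous gates", {
  kin <- list(mode = "dynamic", steady_state = function(V) 1,
              time_constant = function(V) 2)
  expect_equal(gate_derivative(kin, gate = 0, V = -60), 0.5)
  expect_equal(gate_derivative(kin, gate = 1, V = -60), 0)  # fixed point
  inst <- gating_kinetics("TH")$m
  expect_error(gate_derivative(inst, 0.5, -60), "instantaneous")
})

test_that("clamped-voltage relaxation follows the exponential closed form", {
  kin <- gating_kinetics("TH")$h
  V <- -55
  tau <- kin$time_constant(V)
  g <- 0
  dt <- tau / 500
  nstep <- ceiling(10 * tau / dt)
  for (i in seq_len(nstep)) {
    g <- g + dt * gate_derivative(kin, g, V)
  }
  ginf <- kin$steady_state(V)
  # after 10 tau the residual matches exp(-10) of the initial gap
  expect_equal(g, ginf + (0 - ginf) * exp(-nstep * dt / tau), tolerance = 1e-4)
  # and by 16 tau the gate is at steady state to 1e-6
  for (i in seq_len(ceiling(6 * tau / dt))) {
    g <- g + dt * gate_derivative(kin, g, V)
  }
  expect_equal(g, ginf, tolerance = 1e-6)
})

test_that("membrane derivative applies condition-dependent bias and wiring rules", {
  st <- c(V = -60, h = 0.5, n = 0.3, r = 0.5, Ca = 0.1)
  d_h <- membrane_derivative("STN", st, condition = "healthy")
  d_p <- membrane_derivative("STN", st, condition = "pd")
  Cm <- cell_params("STN")$Cm
  # healthy - PD difference is exactly the printed bias drop 29 - 20 uA/cm^2
  expect_equal(d_h - d_p, (29 - 20) / Cm)
  # balanced state: derivative is (-sum I_ion + inputs + bias)/Cm by construction
  ion <- bgdbs:::total_ionic_current("STN", st)
  expect_equal(membrane_derivative("STN", st, I_syn = ion - 29, condition = "healthy"), 0)
  # wiring violations
  expect_error(membrane_derivative("TH", c(V = -60, h = 0.5, r = 0.5), I_dbs = 1),
               "wiring")
  expect_error(membrane_derivative("GPe", st, I_smc = 1), "wiring")
})

test_that("compiled and R derivatives agree for all cell types", {
  set.seed(42)
  for (ct in c("TH", "STN", "GPe", "GPi")) {
    p <- cell_params(ct)
    for (k in 1:5) {
      V <- runif(1, -80, 0)
      st <- if (ct == "TH") {
        c(V = V, h = runif(1), r = runif(1))
      } else {
        c(V = V, h = runif(1), n = runif(1), r = runif(1), Ca = runif(1, 0, 1))
      }
      iext <- runif(1, -10, 10)
      d_r <- cell_derivatives(ct, st,
                              I_syn = if (ct == "TH") iext else 0,
                              I_dbs = if (ct == "TH") 0 else iext,
                              condition = "healthy")
      bias <- if (ct == "TH") 0 else p$bias$healthy
      d_c <- bgdbs:::cpp_cell_deriv(ct, p, unname(st), iext + bias)
      expect_equal(unname(d_r), as.numeric(d_c), tolerance = 1e-12)
    }
  }
})

test_that("isolated thalamic cell rests subthreshold, deterministically", {
  s1 <- init_resting_state("TH")
  s2 <- init_resting_state("TH")
  expect_identical(unclass(s1), unclass(s2))
  expect_length(attr(s1, "spikes"), 0)  # no spikes over the relaxation
  expect_true(s1[["V"]] > -100 && s1[["V"]] < -50)
  # doubling the relaxation barely moves the resting potential
  s3 <- init_resting_state("TH", relax_ms = 1000)
  expect_lt(abs(s3[["V"]] - s1[["V"]]), 0.1)
})

test_that("STN excitability follows the bias current: healthy drive exceeds Parkinsonian", {
  rate <- function(bias) {
    r <- run_single_cell("STN", duration = 2000, dt = 0.01,
                         init = bgdbs:::steady_gate_state("STN", -65),
                         bias = bias, record_every = 50L)
    length(r$spikes)
  }
  expect_gt(rate(29), rate(20))
})

test_that("voltage and gates stay bounded over one second at the default step", {
  for (ct in c("TH", "STN", "GPe", "GPi")) {
    r <- run_single_cell(ct, duration = 1000, dt = 0.01,
                         init = bgdbs:::steady_gate_state(ct, -65),
                         condition = "healthy", record_every = 5L)
    expect_true(all(r$v >= -120 & r$v <= 60))
    ns <- bgdbs:::state_names(ct)
    gates <- r$final_state[setdiff(ns, c("V", "Ca"))]
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("halving the step changes single-cell spike counts by at most one", {
  for (ct in c("STN", "GPe")) {
    init <- bgdbs:::steady_gate_state(ct, -65)
    n1 <- length(run_single_cell(ct, duration = 1000, dt = 0.01, init = init,
                                 condition = "healthy", record_every = 100L)$spikes)
    n2 <- length(run_single_cell(ct, duration = 1000, dt = 0.005, init = init,
                                 condition = "healthy", record_every = 100L)$spikes)
    expect_lte(abs(n1 - n2), 1)
  }
})

test_that("parameter file ships the printed conductance tables", {
  th <- cell_params("TH")$channels
  expect_equal(vapply(th[c("L", "Na", "K", "T")], `[[`, 0, "g"),
               c(L = 0.05, Na = 3, K = 5, T = 5))
  stn <- cell_params("STN")$channels
  expect_equal(vapply(stn[c("L", "Na", "K", "Ca", "T")], `[[`, 0, "g"),
               c(L = 2.25, Na = 37, K = 45, Ca = 2, T = 0.5))
  expect_equal(cell_params("STN")$bias, list(healthy = 29, pd = 20))
  gpe <- cell_params("GPe")$channels
  expect_equal(vapply(gpe[c("L", "Na", "K", "Ca", "T")], `[[`, 0, "g"),
               c(L = 0.1, Na = 120, K = 30, Ca = 0.15, T = 0.5))
  expect_equal(cell_params("GPe")$bias, list(healthy = 20, pd = 8))
  expect_equal(cell_params("GPi")$bias, list(healthy = 22, pd = 12))
})
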