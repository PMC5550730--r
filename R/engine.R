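#' Sensorimotor-cortex drive specification
#'
#' The thalamic population is driven by a stochastic pulse train emulating
#' accumulated sensorimotor-cortex input: rectangular pulses of 3 uA/cm^2 and
#' 5 ms at a mean rate of 14 Hz, with Gaussian inter-pulse intervals of
#' coefficient of variation 0.2 (intervals shorter than the pulse width are
#' redrawn so pulses never overlap).
#'
#' @param amplitude pulse amplitude, uA/cm^2.
#' @param pulse_width pulse duration, ms.
#' @param rate mean pulse rate, Hz.
#' @param cv coefficient of variation of the inter-pulse intervals (>= 0).
#' @param seed integer seed.
#' @return a `bgdbs_smc_spec` list.
#' @export
smc_spec <- function(amplitude = 3, pulse_width = 5, rate = 14, cv = 0.2,
                     seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  stopifnot(rate > 0, pulse_width > 0)
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 rate = rate, cv = cv, seed = as.integer(seed)),
            class = "bgdbs_smc_spec")
}

#' Generate one seeded SMC pulse train
#'
#' Draws inter-pulse intervals from `Normal(1000/rate, (cv * 1000/rate)^2)`,
#' redrawing any interval shorter than the pulse width, until `duration` is
#' covered. Deterministic given the spec's seed. With `cv = 0` the train is
#' perfectly periodic.
#'
#' @param spec a [smc_spec()].
#' @param duration train length, ms (> pulse width).
#' @param dt optional sample step; if given, the sampled current trace is
#'   included.
#' @return a `bgdbs_smc_train` list with `onsets` (ms), the spec fields, and
#'   optionally `trace`.
#' @export
generate_smc_train <- function(spec, duration, dt = NULL) {
  stopifnot(inherits(spec, "bgdbs_smc_spec"), duration > spec$pulse_width)
  mu <- 1000 / spec$rate
  sdv <- spec$cv * mu
  set.seed(spec$seed)
  onsets <- numeric(0)
  t <- 0
  repeat {
    iv <- if (sdv == 0) mu else {
      x <- rnorm(1, mu, sdv)
      while (x < spec$pulse_width) x <- rnorm(1, mu, sdv)
      x
    }
    t <- t + iv
    if (t >= duration) break
    onsets <- c(onsets, t)
  }
  out <- list(onsets = onsets, amplitude = spec$amplitude,
              width = spec$pulse_width, spec = spec)
  if (!is.null(dt)) {
    tt <- seq(0, duration, by = dt)
    I <- numeric(length(tt))
    for (on in onsets) I[tt >= on & tt < on + spec$pulse_width] <- spec$amplitude
    out$trace <- list(t = tt, I = I)
  }
  structure(out, class = "bgdbs_smc_train")
}

# one onset list per TH neuron, seeded reproducibly from the base seed
smc_onsets_population <- function(n, duration, base_seed, amplitude = 3,
                                  pulse_width = 5, rate = 14, cv = 0.2) {
  lapply(seq_len(n), function(i) {
    sp <- smc_spec(amplitude, pulse_width, rate, cv,
                   seed = (as.integer(base_seed) * 1009L + i) %% .Machine$integer.max)
    generate_smc_train(sp, duration)$onsets
  })
}

#' Assemble a validated simulation configuration
#'
#' @param n_per_pop neurons per population (>= 3).
#' @param condition `"healthy"` or `"pd"` (selects STN/GPe/GPi bias currents).
#' @param dbs a `bgdbs_waveform` or `NULL` for no stimulation.
#' @param dbs_targets populations receiving the DBS current; subset of
#'   `c("STN", "GPe", "GPi")`. Default STN only.
#' @param dt integration step, ms.
#' @param duration total simulated time, ms (including the transient).
#' @param transient initial span discarded from spike trains, ms.
#' @param seed integer seed controlling SMC trains, initial conditions and
#'   (in random mode) wiring.
#' @param topology_mode `"structured"` or `"random"`.
#' @param method `"rk4"` or `"euler"`.
#' @param n_record voltage traces kept per population.
#' @param dbs_coupling electrode-to-membrane coupling efficiency scaling
#'   nominal DBS amplitudes (uA) to injected current density (uA/cm^2);
#'   `NULL` uses the calibrated value from the parameter file.
#' @return a `bgdbs_config` list.
#' @export
simulation_config <- function(n_per_pop = 100, condition = c("healthy", "pd"),
                              dbs = NULL, dbs_targets = "STN", dt = 0.01,
                              duration = 1500, transient = 500, seed = 1L,
                              topology_mode = c("structured", "random"),
                              method = c("rk4", "euler"), n_record = 2L,
                              dbs_coupling = NULL) {
  condition <- match.arg(condition)
  topology_mode <- match.arg(topology_mode)
  method <- match.arg(method)
  stopifnot(n_per_pop >= 3, dt > 0, duration > transient, transient >= 0)
  if (!is.null(dbs)) stopifnot(inherits(dbs, "bgdbs_waveform"))
  dbs_targets <- unique(dbs_targets)
  if (!all(dbs_targets %in% c("STN", "GPe", "GPi"))) {
    stop("dbs_targets must be a subset of {STN, GPe, GPi}")
  }
  structure(list(n_per_pop = as.integer(n_per_pop), condition = condition,
                 dbs = dbs, dbs_targets = dbs_targets, dt = dt,
                 duration = duration, transient = transient,
                 seed = as.integer(seed), topology_mode = topology_mode,
                 method = method, n_record = as.integer(n_record),
                 dbs_coupling = dbs_coupling),
            class = "bgdbs_config")
}

# randomized (seeded) initial state for the whole network: membrane
# potentials uniform in [-70, -50] mV, dynamic gates at their steady state
# for the drawn voltage, Ca at a small resting value, synapses at 0.
network_init_state <- function(n, seed) {
  set.seed(as.integer(seed) * 7919L %% .Machine$integer.max)
  draw <- function(cell_type, ncol_) {
    V <- runif(n, -70, -50)
    m <- t(vapply(V, function(v) unname(steady_gate_state(cell_type, v, Ca = 0.1)),
                  numeric(ncol_)))
    m
  }
  list(TH = draw("TH", 3), STN = draw("STN", 5), GPe = draw("GPe", 5),
       GPi = draw("GPi", 5), s = matrix(0, n, 3))
}

#' Run the full network simulation
#'
#' Advances the four populations, synaptic gates, SMC drive and (optionally)
#' the DBS current with the configured fixed-step scheme, detects spikes at
#' -20 mV with a 2 ms refractory window, and discards the transient from the
#' returned spike trains. Deterministic given `(config, seed, dt)`.
#'
#' @param config a [simulation_config()].
#' @return a `bgdbs_result` list: `spikes` (per population, list of spike-time
#'   vectors, transient removed and times re-zeroed to the analysis window),
#'   `window` (analysis span, ms), `dbs_onsets` (cathodic onsets inside the
#'   window, re-zeroed), `v` (recorded voltage matrix), `v_t`, `config`,
#'   `topology`, `clamp_events`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "bgdbs_config"))
  n <- config$n_per_pop
  topo <- build_topology(n, seed = config$seed, mode = config$topology_mode)
  params <- cell_params()
  cells <- params[c("TH", "STN", "GPe", "GPi")]
  sp <- synapse_params()
  key <- function(pre, post) sp[sp$pre == pre & sp$post == post, ]
  kin <- params$synapses$kinetics
  syn <- list(
    g_gpi2th = key("GPi", "TH")$g, g_gpe2stn = key("GPe", "STN")$g,
    g_stn2gpe = key("STN", "GPe")$g, g_gpe2gpe = key("GPe", "GPe")$g,
    g_stn2gpi = key("STN", "GPi")$g, g_gpe2gpi = key("GPe", "GPi")$g,
    E_exc = 0, E_inh = -85,
    alpha_exc = kin$excitatory$alpha, beta_exc = kin$excitatory$beta,
    alpha_inh = kin$inhibitory$alpha, beta_inh = kin$inhibitory$beta,
    gpe_term_sign = params$synapses$gpe_term_sign %||% 1
  )
  smc <- list(onsets = smc_onsets_population(n, config$duration, config$seed),
              amplitude = 3, width = 5)
  if (!is.null(config$dbs)) {
    dbs_dt <- config$dt / 2
    sw <- sample_waveform(config$dbs, dbs_dt, config$duration, align = "grid")
    dbs <- sw$samples * dbs_coupling(config)
    onsets_all <- sw$pulse_onsets
  } else {
    dbs_dt <- config$dt
    dbs <- numeric(0)
    onsets_all <- numeric(0)
  }
  tgt <- c("STN", "GPe", "GPi") %in% config$dbs_targets
  bias <- c(cells$STN$bias[[config$condition]],
            cells$GPe$bias[[config$condition]],
            cells$GPi$bias[[config$condition]])
  init <- network_init_state(n, config$seed)
  topo0 <- lapply(topo[c("gpi2th", "gpe2stn", "stn2gpe", "gpe2gpe",
                         "stn2gpi", "gpe2gpi")], function(m) m - 1L)
  res <- cpp_run_network(cells, topo0, syn, smc, dbs, dbs_dt, tgt, bias,
                         config$dt, config$duration, config$method, init,
                         -20, 2, config$n_record, 10L)
  t0 <- config$transient
  spikes <- lapply(res$spikes, function(pop) {
    lapply(pop, function(s) s[s >= t0] - t0)
  })
  dbs_onsets <- onsets_all[onsets_all >= t0] - t0
  structure(list(spikes = spikes, window = config$duration - t0,
                 dbs_onsets = dbs_onsets, v = res$v, v_t = res$v_t,
                 n_recorded = res$n_recorded,
                 clamp_events = res$clamp_events, config = config,
                 topology = topo),
            class = "bgdbs_result")
}

#' @export
print.bgdbs_result <- function(x, ...) {
  rates <- vapply(x$spikes, function(pop) {
    mean(vapply(pop, length, integer(1))) / (x$window / 1000)
  }, numeric(1))
  cat(sprintf("bgdbs simulation: n = %d/pop, %s, %s, %g ms window\n",
              x$config$n_per_pop, x$config$condition,
              if (is.null(x$config$dbs)) "no DBS" else
                paste0("DBS ", x$config$dbs$name %||% "custom"),
              x$window))
  cat("  mean rates (Hz): ",
      paste(sprintf("%s %.1f", names(rates), rates), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population mean firing rates of a simulation result
#'
#' @param result a `bgdbs_result`.
#' @return named numeric vector of mean per-neuron rates, Hz.
#' @export
population_rates <- function(result) {
  vapply(result$spikes, function(pop) {
    mean(vapply(pop, length, integer(1))) / (result$window / 1000)
  }, numeric(1))
}

#' Detect spikes in a voltage trace
#'
#' A spike is a strict upward crossing of the threshold (previous sample
#' below, current sample above); crossings within the refractory window of
#' the previous accepted spike are suppressed. A trace that touches the
#' threshold without exceeding it yields no spike.
#'
#' @param v voltage samples, mV (uniformly sampled).
#' @param dt sample step, ms.
#' @param threshold detection threshold, mV.
#' @param refractory dead time after each spike, ms.
#' @param t0 time of the first sample, ms.
#' @return a `bgdbs_spiketrain`: numeric spike times with attributes
#'   `threshold` and `refractory`.
#' @export
detect_spikes <- function(v, dt, threshold = -20, refractory = 2, t0 = 0) {
  n <- length(v)
  if (n < 2) return(structure(numeric(0), threshold = threshold,
                              refractory = refractory,
                              class = "bgdbs_spiketrain"))
  up <- which(v[-n] < threshold & v[-1] > threshold)
  times <- t0 + up * dt
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  structure(keep, threshold = threshold, refractory = refractory,
            class = "bgdbs_spiketrain")
}

#' Electrode-to-membrane coupling efficiency in effect
#'
#' Nominal DBS amplitudes (uA) are scaled by this dimensionless factor to
#' obtain the current density injected into targeted compartments (uA/cm^2).
#' The shipped value is calibrated against the rectangular delay-threshold
#' anchor; see the methods vignette.
#'
#' @param config optional `bgdbs_config` carrying an override.
#' @return scalar coupling efficiency.
#' @export
dbs_coupling <- function(config = NULL) {
  if (!is.null(config) && !is.null(config$dbs_coupling)) return(config$dbs_coupling)
  cell_params()$stimulation$dbs_coupling
}
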