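#' Run one study condition
#'
#' Convenience wrapper: healthy or Parkinsonian network, optionally with one
#' of the six DBS presets on the STN, at the scaled defaults (desk-scale
#' network, 1 s analysis window after a 0.5 s transient).
#'
#' @param condition `"healthy"`, `"pd"`, or a preset name (presets run on the
#'   PD network, the stimulation setting of the study).
#' @param n_per_pop neurons per population.
#' @param seed integer seed.
#' @param duration,transient simulated span and discarded transient, ms.
#' @param dt integration step, ms.
#' @param method `"rk4"` or `"euler"`.
#' @return a `bgdbs_result`.
#' @export
run_condition <- function(condition, n_per_pop = 100, seed = 1L,
                          duration = 1500, transient = 500, dt = 0.01,
                          method = "rk4") {
  presets <- preset_names()
  if (condition %in% c("healthy", "pd")) {
    cfg <- simulation_config(n_per_pop, condition = condition, dbs = NULL,
                             dt = dt, duration = duration,
                             transient = transient, seed = seed,
                             method = method)
  } else {
    condition <- match.arg(condition, presets)
    cfg <- simulation_config(n_per_pop, condition = "pd",
                             dbs = make_preset(condition),
                             dbs_targets = "STN", dt = dt,
                             duration = duration, transient = transient,
                             seed = seed, method = method)
  }
  run_simulation(cfg)
}

#' Default cost-evaluation window
#'
#' The cost comparisons integrate energy and count misses over a common
#' window of 40 DBS pulses (about 307.7 ms at 130 Hz); see the methods
#' vignette for the rationale behind this convention.
#'
#' @param frequency DBS frequency, Hz.
#' @param n_pulses pulses in the window.
#' @return window length, ms.
#' @export
cost_window <- function(frequency = 130, n_pulses = 40) {
  n_pulses * 1000 / frequency
}

#' Cost decomposition of one DBS simulation
#'
#' Eq-style cost over a common window: waveform energy plus 3 nJ per mean
#' per-neuron miss on the target population.
#'
#' @param result a `bgdbs_result` run with DBS.
#' @param window cost window, ms (default [cost_window()]).
#' @param Z impedance, kOhm.
#' @return a `bgdbs_cost` with the miss statistics attached.
#' @export
cost_from_result <- function(result, window = NULL, Z = 1) {
  cfg <- result$config
  if (is.null(cfg$dbs)) stop("simulation was run without DBS")
  if (is.null(window)) window <- cost_window(cfg$dbs$frequency)
  if (window > result$window) stop("cost window exceeds the analysis window")
  period <- 1000 / cfg$dbs$frequency
  onsets <- result$dbs_onsets
  onsets <- onsets[onsets + period <= window + 1e-9]
  per <- vapply(result$spikes[[cfg$dbs_targets[1]]], function(s) {
    count_misses(onsets, s, period)
  }, integer(1))
  sw <- sample_waveform(cfg$dbs, dt = 0.005, duration = window,
                        align = "midpoint")
  out <- dbs_cost(sw, M = mean(per), Z = Z, window = window)
  out$miss_per_neuron <- per
  out$n_pulses <- length(onsets)
  out
}

#' Energy / miss / cost comparison across presets and network sizes
#'
#' Runs the PD network under each preset for each size and seed and tabulates
#' the cost decomposition.
#'
#' @param sizes network sizes (neurons per population).
#' @param presets preset names.
#' @param seeds integer seeds.
#' @param window cost window, ms.
#' @param ... passed to [run_condition()].
#' @return data.frame with one row per (preset, size, seed).
#' @export
energy_comparison <- function(sizes = 100, presets = preset_names(),
                              seeds = 1:3, window = NULL, ...) {
  rows <- list()
  for (size in sizes) {
    for (pr in presets) {
      for (sd_ in seeds) {
        res <- run_condition(pr, n_per_pop = size, seed = sd_, ...)
        co <- cost_from_result(res, window = window)
        rows[[length(rows) + 1]] <- data.frame(
          preset = pr, size = size, seed = sd_, energy_nJ = co$energy,
          misses = co$M, cost_nJ = co$C, n_pulses = co$n_pulses)
      }
    }
  }
  do.call(rbind, rows)
}

#' Seed-median percent cost reduction between two presets
#'
#' @param tab output of [energy_comparison()].
#' @param preset,reference preset names; reduction of `preset` relative to
#'   `reference`.
#' @param size network size to compare at (default: the largest present).
#' @return percent reduction (positive = `preset` cheaper).
#' @export
cost_reduction <- function(tab, preset, reference, size = max(tab$size)) {
  pick <- function(p) {
    x <- tab[tab$preset == p & tab$size == size, ]
    x[order(x$seed), "cost_nJ"]
  }
  a <- pick(preset)
  b <- pick(reference)
  stopifnot(length(a) == length(b), length(a) > 0)
  100 * median((b - a) / b)
}

#' Minimal eliciting amplitude as a function of interphase delay
#'
#' For a quiescent, network-loaded model STN cell (Parkinsonian bias with the
#' mean pallidal inhibitory conductance load), bisects per interphase delay
#' the minimal nominal cathodic amplitude whose single biphasic pulse elicits
#' an action potential, using the 10:1 cathodic:anodic amplitude ratio and
#' 3.3:1 anodic:cathodic width ratio. Nominal amplitudes are converted to
#' injected current density through the calibrated electrode coupling
#' ([dbs_coupling()]). The delay threshold is the smallest delay whose
#' minimal amplitude does not exceed the 200 uA reference.
#'
#' @param shape phase shape of the waveform family (`"gaussian"` for GDG,
#'   `"half_sine"` for SDS, `"rectangular"` for PDP).
#' @param delays delay axis, ms.
#' @param amp_max bisection cap on the nominal amplitude, uA.
#' @param tol_amp bisection resolution, uA.
#' @param cathodic_width cathodic width, ms.
#' @param reference_amp amplitude defining the delay threshold, uA.
#' @param detect_window evoked-spike window after cathodic onset, ms.
#' @param dt integration step, ms.
#' @param g_load,E_load,bias loading of the target cell: static afferent
#'   conductance (mS/cm^2), its reversal (mV), and the bias current
#'   (default the Parkinsonian STN bias).
#' @return a `bgdbs_threshold_curve` list: `delays`, `min_amp` (nominal uA,
#'   NA where the cap was insufficient), `delay_threshold`, `shape`,
#'   `reference_amp`.
#' @export
delay_threshold_curve <- function(shape, delays = seq(0, 1.2, by = 0.05),
                                  amp_max = 1000, tol_amp = 1,
                                  cathodic_width = 0.3, reference_amp = 200,
                                  detect_window = 5, dt = 0.005,
                                  g_load = 1.0, E_load = -85, bias = NULL) {
  if (is.null(bias)) bias <- cell_params("STN")$bias$pd
  init <- loaded_stn_rest(bias, g_load, E_load)
  kap <- dbs_coupling()
  elicits <- function(amp, delay) {
    spec <- waveform_spec(
      cathodic = phase_spec(shape, amplitude = amp * kap,
                            width = cathodic_width),
      delay = delay,
      anodic = phase_spec(shape, amplitude = -amp * kap / 10,
                          width = 3.3 * cathodic_width),
      frequency = 2  # single pulse in a long period
    )
    dur <- detect_window + 5
    sw <- sample_waveform(spec, dt = dt / 2, duration = dur, align = "grid")
    res <- run_single_cell("STN", I_inj = sw$samples, dt_inj = dt / 2,
                           duration = dur, dt = dt, init = init, bias = bias,
                           g_load = g_load, E_load = E_load,
                           record_every = 10L)
    any(res$spikes < detect_window)
  }
  min_amp <- vapply(delays, function(dl) {
    if (!elicits(amp_max, dl)) return(NA_real_)
    lo <- 0; hi <- amp_max
    while (hi - lo > tol_amp) {
      mid <- (lo + hi) / 2
      if (elicits(mid, dl)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  idx <- which(!is.na(min_amp) & min_amp <= reference_amp)
  structure(list(delays = delays, min_amp = min_amp,
                 delay_threshold = if (length(idx)) delays[min(idx)] else NA_real_,
                 shape = shape, reference_amp = reference_amp),
            class = "bgdbs_threshold_curve")
}

# relaxed state of the network-loaded quiescent STN cell (cached per loading)
loaded_stn_rest <- function(bias, g_load = 1.0, E_load = -85) {
  key <- sprintf("stn_rest_%g_%g_%g", bias, g_load, E_load)
  if (is.null(.bgdbs_env[[key]])) {
    st <- run_single_cell("STN", duration = 500, dt = 0.01,
                          init = steady_gate_state("STN", -65), bias = bias,
                          g_load = g_load, E_load = E_load,
                          record_every = 10L)
    .bgdbs_env[[key]] <- st$final_state
  }
  .bgdbs_env[[key]]
}

#' Delay-threshold curves for the three delay presets
#'
#' @param presets subset of `c("PDP", "SDS", "GDG")`.
#' @param ... passed to [delay_threshold_curve()].
#' @return named list of `bgdbs_threshold_curve`s.
#' @export
delay_threshold_curves <- function(presets = c("GDG", "SDS", "PDP"), ...) {
  shapes <- c(PDP = "rectangular", SDS = "half_sine", GDG = "gaussian")
  out <- lapply(presets, function(p) delay_threshold_curve(shapes[[p]], ...))
  names(out) <- presets
  out
}

#' PLV of the DBS drive with population firing over a (delay, amplitude) grid
#'
#' For each grid cell, simulates the PD network under the given waveform
#' family at 130 Hz and computes the phase-locking value between the sampled
#' DBS current and the population firing-rate signal of the requested
#' population.
#'
#' @param population `"STN"`, `"GPe"`, or `"GPi"`.
#' @param shape waveform family shape.
#' @param delays,amplitudes grid axes (ms, uA/cm^2).
#' @param n_per_pop,seed,duration,transient scaled run settings.
#' @param ... passed to [run_simulation()] config.
#' @return matrix of PLV values, delays x amplitudes.
#' @export
plv_heatmap <- function(population = "STN", shape = "gaussian",
                        delays = seq(0, 1.2, by = 0.3),
                        amplitudes = seq(190, 210, by = 10),
                        n_per_pop = 20, seed = 1L, duration = 1000,
                        transient = 400, ...) {
  out <- matrix(NA_real_, length(delays), length(amplitudes),
                dimnames = list(paste0("DL", delays), paste0("A", amplitudes)))
  for (di in seq_along(delays)) {
    for (ai in seq_along(amplitudes)) {
      spec <- waveform_spec(
        cathodic = phase_spec(shape, amplitude = amplitudes[ai], width = 0.3),
        delay = delays[di],
        anodic = phase_spec(shape, amplitude = -amplitudes[ai] / 10,
                            width = 1),
        frequency = 130
      )
      cfg <- simulation_config(n_per_pop, condition = "pd", dbs = spec,
                               dbs_targets = "STN", duration = duration,
                               transient = transient, seed = seed, ...)
      res <- run_simulation(cfg)
      dtm <- 0.025  # fine enough to resolve the 0.3 ms cathodic phase
      drive <- sample_waveform(spec, dt = dtm, duration = res$window,
                               align = "midpoint")$samples
      rate <- population_rate_signal_dense(res$spikes[[population]],
                                           res$window, dtm)
      drive <- drive[seq_len(min(length(drive), length(rate)))]
      rate <- rate[seq_len(length(drive))]
      out[di, ai] <- plv(drive, rate)$plv
    }
  }
  out
}

# population mean smoothed rate on a dense grid (for phase analyses)
population_rate_signal_dense <- function(trains, duration, dt = 1,
                                         kernel_sd = 10) {
  all_spikes <- sort(unlist(trains))
  spike_rate_signal(all_spikes, duration, dt = dt, kernel_sd = kernel_sd) /
    max(length(trains), 1)
}

#' Synchronization-level table across study conditions
#'
#' GPi synchronization level for healthy, PD, and the six DBS presets,
#' seed-median with inter-quartile range.
#'
#' @param conditions character vector of conditions/presets.
#' @param seeds integer seeds.
#' @param n_per_pop neurons per population (>= 100 for the headline claims).
#' @param population population whose SL is computed.
#' @param ... passed to [run_condition()].
#' @return data.frame with one row per condition: median SL and IQR.
#' @export
table_sl <- function(conditions = c("healthy", "pd", preset_names()),
                     seeds = 1:3, n_per_pop = 100, population = "GPi", ...) {
  rows <- lapply(conditions, function(cond) {
    sls <- vapply(seeds, function(sd_) {
      res <- run_condition(cond, n_per_pop = n_per_pop, seed = sd_, ...)
      synchronization_level(res$spikes[[population]], res$window)$sl
    }, numeric(1))
    data.frame(condition = cond, sl_median = median(sls),
               sl_iqr = stats::IQR(sls), n_seeds = length(seeds))
  })
  do.call(rbind, rows)
}

#' Generate the seeded test-fixture bundle
#'
#' Writes small plain-text fixtures used by regression tests: a 3-neuron
#' micro-network topology, constructed spike trains with known SL and PLV
#' values, sampled preset waveforms, and a manifest. Byte-identical across
#' regenerations with the same seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the manifest, invisibly.
#' @export
generate_fixtures <- function(dir = tempfile("bgdbs_fixtures"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  topo <- build_topology(3, seed = seed, mode = "structured")
  topology_to_json(topo, file.path(dir, "micro_topology.json"))
  # identical non-constant AP-count trains -> SL = 1
  base <- sort(runif(30, 0, 300))
  ident <- replicate(5, base, simplify = FALSE)
  write.csv(data.frame(neuron = rep(seq_along(ident), each = length(base)),
                       t_ms = unlist(ident)),
            file.path(dir, "identical_trains.csv"), row.names = FALSE)
  # quadrature pair: cos and sin -> PLV 1, lag pi/2
  tt <- seq(0, 1, length.out = 1000)
  write.csv(data.frame(t = tt, y_cos = cos(2 * pi * 10 * tt),
                       y_sin = sin(2 * pi * 10 * tt)),
            file.path(dir, "quadrature_pair.csv"), row.names = FALSE)
  for (p in preset_names()) {
    sampled_to_csv(sample_waveform(make_preset(p), dt = 0.01, duration = 10),
                   file.path(dir, paste0("preset_", p, ".csv")))
  }
  manifest <- list(seed = as.integer(seed),
                   files = sort(list.files(dir)),
                   expected = list(identical_trains_sl = 1,
                                   quadrature_plv = 1,
                                   quadrature_lag = pi / 2))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
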