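#' @useDynLib bgdbs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median cor pt sd rnorm runif quantile
#' @importFrom utils write.csv
NULL

.bgdbs_env <- new.env(parent = emptyenv())

sigm <- function(x) 1 / (1 + exp(-x))

#' Load the per-population cell parameter tables
#'
#' Conductances, reversal potentials, capacitances and condition-dependent
#' bias currents for the four modeled populations (TH, STN, GPe, GPi), read
#' from the versioned parameter file shipped in `inst/extdata/cell_params.json`.
#' The gating kinetics functional forms follow the Rubin & Terman (2004) /
#' So et al. (2012) model family; see [gating_kinetics()].
#'
#' @param cell_type one of `"TH"`, `"STN"`, `"GPe"`, `"GPi"`, or `NULL` for the
#'   full table (including the synapse section).
#' @param file optional path to an alternative parameter file with the same
#'   schema.
#' @return a named list of parameters.
#' @export
cell_params <- function(cell_type = NULL, file = NULL) {
  if (is.null(file)) {
    if (is.null(.bgdbs_env$params)) {
      path <- system.file("extdata", "cell_params.json", package = "bgdbs")
      .bgdbs_env$params <- jsonlite::read_json(path, simplifyVector = FALSE)
    }
    all <- .bgdbs_env$params
  } else {
    all <- jsonlite::read_json(file, simplifyVector = FALSE)
  }
  if (is.null(cell_type)) return(all)
  cell_type <- match.arg(cell_type, c("TH", "STN", "GPe", "GPi"))
  all[[cell_type]]
}

state_names <- function(cell_type) {
  if (cell_type == "TH") c("V", "h", "r") else c("V", "h", "n", "r", "Ca")
}

#' Gating kinetics for one population
#'
#' Returns, for each gating variable of the cell type, its steady-state curve
#' and (for dynamic gates) voltage-dependent time constant, in the form the
#' membrane equations consume. Instantaneous gates (`mode = "instantaneous"`)
#' are evaluated at the current voltage rather than integrated.
#'
#' @param cell_type one of `"TH"`, `"STN"`, `"GPe"`, `"GPi"`.
#' @return a named list; each element has `steady_state(V)`, `mode`, and for
#'   dynamic gates `time_constant(V)` in ms (with any phi factor folded in).
#' @export
gating_kinetics <- function(cell_type) {
  cell_type <- match.arg(cell_type, c("TH", "STN", "GPe", "GPi"))
  if (cell_type == "TH") {
    return(list(
      m = list(mode = "instantaneous",
               steady_state = function(V) sigm((V + 37) / 7)),
      h = list(mode = "dynamic",
               steady_state = function(V) sigm(-(V + 41) / 4),
               time_constant = function(V) {
                 1 / (0.128 * exp(-(V + 46) / 18) + 4 * sigm((V + 23) / 5))
               }),
      p = list(mode = "instantaneous",
               steady_state = function(V) sigm((V + 60) / 6.2)),
      r = list(mode = "dynamic",
               steady_state = function(V) sigm(-(V + 84) / 4),
               time_constant = function(V) 0.15 * (28 + exp(-(V + 25) / 10.5)))
    ))
  }
  if (cell_type == "STN") {
    phi <- cell_params("STN")$phi
    return(list(
      m = list(mode = "instantaneous",
               steady_state = function(V) sigm((V + 30) / 15)),
      h = list(mode = "dynamic",
               steady_state = function(V) sigm(-(V + 39) / 3.1),
               time_constant = function(V)
                 (1 + 500 * sigm(-(V + 57) / 3)) / phi$h),
      n = list(mode = "dynamic",
               steady_state = function(V) sigm((V + 32) / 8),
               time_constant = function(V)
                 (1 + 100 * sigm(-(V + 80) / 26)) / phi$n),
      r = list(mode = "dynamic",
               steady_state = function(V) sigm(-(V + 67) / 2),
               time_constant = function(V)
                 (40 + 17.5 * sigm(-(V + 68) / 2.2)) / phi$r),
      a = list(mode = "instantaneous",
               steady_state = function(V) sigm((V + 63) / 7.8)),
      b = list(mode = "instantaneous_of_r",
               steady_state = function(r) sigm((r - 0.4) / 0.1) - sigm(-4)),
      s = list(mode = "instantaneous",
               steady_state = function(V) sigm((V + 39) / 8))
    ))
  }
  # GPe / GPi share forms
  phi <- cell_params(cell_type)$phi
  list(
    m = list(mode = "instantaneous",
             steady_state = function(V) sigm((V + 37) / 10)),
    h = list(mode = "dynamic",
             steady_state = function(V) sigm(-(V + 58) / 12),
             time_constant = function(V)
               (0.05 + 0.27 * sigm(-(V + 40) / 12)) / phi$h),
    n = list(mode = "dynamic",
             steady_state = function(V) sigm((V + 50) / 14),
             time_constant = function(V)
               (0.05 + 0.27 * sigm(-(V + 40) / 12)) / phi$n),
    r = list(mode = "dynamic",
             steady_state = function(V) sigm(-(V + 70) / 2),
             time_constant = function(V) rep(30 / phi$r, length(V))),
    a = list(mode = "instantaneous",
             steady_state = function(V) sigm((V + 57) / 2)),
    s = list(mode = "instantaneous",
             steady_state = function(V) sigm((V + 35) / 2))
  )
}

#' Ionic current density through one channel
#'
#' Computes `g * m^M * h^N * (V - E)`, the ohmic current density of a gated
#' conductance. Positive values enter the membrane equation with a leading
#' minus sign (outward/hyperpolarizing when positive).
#'
#' @param channel a list with `g` (mS/cm^2), `E` (mV), and exponents `M`, `N`
#'   (as returned in `cell_params(type)$channels`).
#' @param V membrane potential, mV.
#' @param m,h activation / inactivation gate values in `[0, 1]` (defaults 1,
#'   appropriate for ungated channels).
#' @return current density, uA/cm^2.
#' @export
ionic_current <- function(channel, V, m = 1, h = 1) {
  stopifnot(is.list(channel), !is.null(channel$g), !is.null(channel$E))
  M <- if (is.null(channel$M)) 0 else channel$M
  N <- if (is.null(channel$N)) 0 else channel$N
  channel$g * m^M * h^N * (V - channel$E)
}

#' Relaxation derivative of a dynamic gating variable
#'
#' `d(gate)/dt = (steady_state(V) - gate) / time_constant(V)`.
#'
#' @param kinetics one element of [gating_kinetics()] with `mode = "dynamic"`.
#' @param gate current gate value in `[0, 1]`.
#' @param V membrane potential, mV.
#' @return derivative in 1/ms.
#' @export
gate_derivative <- function(kinetics, gate, V) {
  if (!identical(kinetics$mode, "dynamic")) {
    stop("gate_derivative() applies only to dynamic gates; ",
         "instantaneous gates are evaluated, not integrated")
  }
  (kinetics$steady_state(V) - gate) / kinetics$time_constant(V)
}

# Total ionic current (sum of -I_ion terms is -total_ionic_current)
total_ionic_current <- function(cell_type, state) {
  p <- cell_params(cell_type)
  kin <- gating_kinetics(cell_type)
  ch <- p$channels
  V <- state[["V"]]
  if (cell_type == "TH") {
    h <- state[["h"]]; r <- state[["r"]]
    IL <- ionic_current(ch$L, V)
    INa <- ionic_current(ch$Na, V, m = kin$m$steady_state(V), h = h)
    IK <- ionic_current(ch$K, V, m = 0.75 * (1 - h))
    IT <- ionic_current(ch$T, V, m = kin$p$steady_state(V), h = r)
    return(IL + INa + IK + IT)
  }
  h <- state[["h"]]; n <- state[["n"]]; r <- state[["r"]]; Ca <- state[["Ca"]]
  IL <- ionic_current(ch$L, V)
  INa <- ionic_current(ch$Na, V, m = kin$m$steady_state(V), h = h)
  IK <- ionic_current(ch$K, V, m = n)
  ICa <- ionic_current(ch$Ca, V, m = kin$s$steady_state(V))
  IT <- if (cell_type == "STN") {
    ionic_current(ch$T, V, m = kin$a$steady_state(V),
                  h = kin$b$steady_state(r))
  } else {
    ionic_current(ch$T, V, m = kin$a$steady_state(V), h = r)
  }
  IAHP <- p$ahp$g * (V - ch$K$E) * Ca / (Ca + p$ahp$k1)
  IL + INa + IK + ICa + IT + IAHP
}

#' Membrane potential derivative of one cell
#'
#' `dV/dt = (-sum(I_ion) + I_syn + I_ext + I_bias) / C_m`, where `I_syn` is the
#' already-signed sum of afferent synaptic currents (the caller negates
#' [synaptic_current()] values) and `I_ext` is the sensorimotor-cortex drive
#' (TH only, `I_smc`) or the DBS current (STN/GPe/GPi, `I_dbs`). TH has no
#' bias term.
#'
#' @param cell_type one of `"TH"`, `"STN"`, `"GPe"`, `"GPi"`.
#' @param state named state vector: TH `c(V, h, r)`; others `c(V, h, n, r, Ca)`.
#' @param I_syn signed afferent synaptic current sum, uA/cm^2.
#' @param I_smc sensorimotor-cortex current, uA/cm^2 (TH only).
#' @param I_dbs DBS current, uA/cm^2 (STN/GPe/GPi only).
#' @param condition `"healthy"` or `"pd"`, selects the bias current.
#' @return dV/dt in mV/ms.
#' @export
membrane_derivative <- function(cell_type, state, I_syn = 0, I_smc = 0,
                                I_dbs = 0, condition = c("healthy", "pd")) {
  cell_type <- match.arg(cell_type, c("TH", "STN", "GPe", "GPi"))
  condition <- match.arg(condition)
  if (cell_type == "TH" && I_dbs != 0) {
    stop("model wiring violation: TH neurons receive no DBS term")
  }
  if (cell_type != "TH" && I_smc != 0) {
    stop("model wiring violation: only TH neurons receive the SMC term")
  }
  p <- cell_params(cell_type)
  bias <- if (cell_type == "TH") 0 else p$bias[[condition]]
  (-total_ionic_current(cell_type, state) + I_syn + I_smc + I_dbs + bias) / p$Cm
}

#' Full state derivative of one cell (R reference implementation)
#'
#' Pure-R mirror of the compiled integrator's right-hand side, used for unit
#' tests and for building steady-state initial conditions.
#'
#' @inheritParams membrane_derivative
#' @return named derivative vector matching `state`.
#' @export
cell_derivatives <- function(cell_type, state, I_syn = 0, I_smc = 0,
                             I_dbs = 0, condition = "healthy") {
  kin <- gating_kinetics(cell_type)
  p <- cell_params(cell_type)
  V <- state[["V"]]
  dV <- membrane_derivative(cell_type, state, I_syn, I_smc, I_dbs, condition)
  if (cell_type == "TH") {
    d <- c(V = dV,
           h = gate_derivative(kin$h, state[["h"]], V),
           r = gate_derivative(kin$r, state[["r"]], V))
    return(d)
  }
  ch <- p$channels
  ICa <- ionic_current(ch$Ca, V, m = kin$s$steady_state(V))
  IT <- if (cell_type == "STN") {
    ionic_current(ch$T, V, m = kin$a$steady_state(V),
                  h = kin$b$steady_state(state[["r"]]))
  } else {
    ionic_current(ch$T, V, m = kin$a$steady_state(V), h = state[["r"]])
  }
  c(V = dV,
    h = gate_derivative(kin$h, state[["h"]], V),
    n = gate_derivative(kin$n, state[["n"]], V),
    r = gate_derivative(kin$r, state[["r"]], V),
    Ca = p$ca$eps * (-ICa - IT - p$ca$kca * state[["Ca"]]))
}

# gates at steady state for a given V (dynamic gates only), Ca at its
# fixed point estimate
steady_gate_state <- function(cell_type, V, Ca = 0.1) {
  kin <- gating_kinetics(cell_type)
  if (cell_type == "TH") {
    return(c(V = V, h = kin$h$steady_state(V), r = kin$r$steady_state(V)))
  }
  c(V = V, h = kin$h$steady_state(V), n = kin$n$steady_state(V),
    r = kin$r$steady_state(V), Ca = Ca)
}

#' Relaxed (resting) state of an isolated cell
#'
#' Integrates the isolated cell (no synaptic, SMC, or DBS input; bias per
#' condition) from a subthreshold start until transients decay, and returns
#' the final state. For intrinsically silent parameter sets this is the
#' zero-current fixed point; for pacemaking cells it is a point on the
#' unperturbed limit cycle. Deterministic given parameters.
#'
#' @inheritParams membrane_derivative
#' @param relax_ms relaxation duration, ms.
#' @param dt integration step, ms.
#' @return named state vector (class `bgdbs_state`) with attribute `spikes`
#'   (spike times during the relaxation).
#' @export
init_resting_state <- function(cell_type, condition = c("healthy", "pd"),
                               relax_ms = 500, dt = 0.01) {
  cell_type <- match.arg(cell_type, c("TH", "STN", "GPe", "GPi"))
  condition <- match.arg(condition)
  p <- cell_params(cell_type)
  bias <- if (cell_type == "TH") 0 else p$bias[[condition]]
  init <- steady_gate_state(cell_type, -65)
  res <- cpp_run_single(cell_type, p, bias, numeric(0), dt, dt, relax_ms,
                        "rk4", unname(init), -20, 2, 10L, 0, -85)
  out <- res$final_state
  names(out) <- state_names(cell_type)
  vtail <- res$v[res$t >= relax_ms - 100]
  if (mean(vtail) < -100 || mean(vtail) > 0) {
    stop(sprintf("initialization failed for %s: mean V over last 100 ms = %.1f mV (expected in [-100, 0])",
                 cell_type, mean(vtail)))
  }
  structure(out, spikes = res$spikes, class = "bgdbs_state")
}

#' Simulate one isolated cell under an arbitrary injected current
#'
#' Thin wrapper over the compiled single-cell integrator. The injected trace
#' `I_inj` is sampled on the integration grid (`I_inj[k]` applies at
#' `t = (k-1) * dt_inj`); a constant `bias` is added on top.
#'
#' @inheritParams init_resting_state
#' @param I_inj numeric vector of injected current samples, uA/cm^2.
#' @param dt_inj sampling step of `I_inj`, ms (use `dt/2` with RK4 so the
#'   half-step evaluations see the true waveform).
#' @param duration simulated time, ms.
#' @param init initial state (defaults to [init_resting_state()]).
#' @param method `"rk4"` or `"euler"`.
#' @param bias constant current added throughout, uA/cm^2; `NULL` uses the
#'   condition's bias.
#' @param threshold,refractory spike detection threshold (mV) and dead time (ms).
#' @param record_every store every k-th voltage sample.
#' @param g_load,E_load static afferent conductance load (mS/cm^2) and its
#'   reversal (mV); emulates mean synaptic loading of an in-network cell.
#' @return list with `t`, `v`, `spikes`, `final_state`.
#' @export
run_single_cell <- function(cell_type, I_inj = numeric(0), dt_inj = 0.005,
                            duration = 1000, dt = 0.01, init = NULL,
                            condition = "healthy", bias = NULL,
                            method = c("rk4", "euler"), threshold = -20,
                            refractory = 2, record_every = 1L, g_load = 0,
                            E_load = -85) {
  cell_type <- match.arg(cell_type, c("TH", "STN", "GPe", "GPi"))
  method <- match.arg(method)
  p <- cell_params(cell_type)
  if (is.null(bias)) {
    bias <- if (cell_type == "TH") 0 else p$bias[[match.arg(condition, c("healthy", "pd"))]]
  }
  if (is.null(init)) {
    init <- init_resting_state(cell_type, match.arg(condition, c("healthy", "pd")))
  }
  res <- cpp_run_single(cell_type, p, bias, I_inj, dt_inj, dt, duration,
                        method, unname(unclass(init)), threshold, refractory,
                        as.integer(record_every), g_load, E_load)
  names(res$final_state) <- state_names(cell_type)
  res
}
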