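#' Construct one phase of a biphasic stimulation pulse
#'
#' @param shape `"rectangular"`, `"half_sine"`, or `"gaussian"`.
#' @param amplitude peak current, uA/cm^2, signed. The cathodic
#'   (depolarizing) phase is stored as positive current injected into the
#'   compartment, the anodic recovery phase as negative.
#' @param width phase duration, ms (> 0).
#' @param sigma Gaussian standard deviation, ms; default `width/6` so the
#'   bell's +-3 sigma support spans the phase. The bell peaks at `amplitude`
#'   at the phase midpoint and is truncated at the phase edges.
#' @return a `bgdbs_phase` list.
#' @export
phase_spec <- function(shape = c("rectangular", "half_sine", "gaussian"),
                       amplitude, width, sigma = width / 6) {
  shape <- match.arg(shape)
  stopifnot(width > 0, sigma > 0)
  structure(list(shape = shape, amplitude = amplitude, width = width,
                 sigma = sigma),
            class = "bgdbs_phase")
}

#' Construct a full DBS waveform specification
#'
#' A pulse is a cathodic phase, then a zero-current interphase delay, then an
#' anodic phase, repeated at `frequency`. The whole pulse must fit within one
#' period.
#'
#' @param cathodic,anodic [phase_spec()] objects.
#' @param delay interphase delay, ms (>= 0).
#' @param frequency pulse repetition rate, Hz.
#' @param name optional tag.
#' @return a `bgdbs_waveform` list.
#' @export
waveform_spec <- function(cathodic, delay, anodic, frequency = 130,
                          name = NULL) {
  stopifnot(inherits(cathodic, "bgdbs_phase"), inherits(anodic, "bgdbs_phase"),
            delay >= 0, frequency > 0)
  period <- 1000 / frequency
  if (cathodic$width + delay + anodic$width >= period) {
    stop(sprintf("pulse (%.3f ms) does not fit in the %.3f ms period at %g Hz",
                 cathodic$width + delay + anodic$width, period, frequency))
  }
  structure(list(cathodic = cathodic, delay = delay, anodic = anodic,
                 frequency = frequency, name = name),
            class = "bgdbs_waveform")
}

#' The six study waveform presets
#'
#' All presets share a 200 uA/cm^2 x 0.3 ms cathodic phase, a -20 uA/cm^2 x
#' 1 ms anodic phase, and 130 Hz repetition. The delay variants (PDP, SDS,
#' GDG) insert a 0.7 ms interphase delay; Pulse, Sinusoid, and Gaussian use
#' no delay. Shapes are rectangular, half-sine, and Gaussian respectively.
#'
#' @param name one of `"Pulse"`, `"PDP"`, `"Sinusoid"`, `"SDS"`, `"Gaussian"`,
#'   `"GDG"`.
#' @return a `bgdbs_waveform`.
#' @export
make_preset <- function(name = c("Pulse", "PDP", "Sinusoid", "SDS",
                                 "Gaussian", "GDG")) {
  name <- match.arg(name)
  shape <- switch(name,
                  Pulse = , PDP = "rectangular",
                  Sinusoid = , SDS = "half_sine",
                  Gaussian = , GDG = "gaussian")
  delay <- if (name %in% c("PDP", "SDS", "GDG")) 0.7 else 0
  waveform_spec(
    cathodic = phase_spec(shape, amplitude = 200, width = 0.3),
    delay = delay,
    anodic = phase_spec(shape, amplitude = -20, width = 1),
    frequency = 130, name = name
  )
}

#' @export
preset_names <- function() c("Pulse", "PDP", "Sinusoid", "SDS", "Gaussian", "GDG")

# value of one phase at offset u in [0, width) from phase start
phase_value <- function(phase, u) {
  out <- numeric(length(u))
  inside <- u >= 0 & u < phase$width
  ui <- u[inside]
  out[inside] <- switch(phase$shape,
    rectangular = phase$amplitude,
    half_sine = phase$amplitude * sin(pi * ui / phase$width),
    gaussian = phase$amplitude *
      exp(-((ui - phase$width / 2)^2) / (2 * phase$sigma^2))
  )
  out
}

# one full pulse evaluated at offset u from cathodic onset
pulse_value <- function(spec, u) {
  v <- phase_value(spec$cathodic, u)
  a0 <- spec$cathodic$width + spec$delay
  v + phase_value(spec$anodic, u - a0)
}

#' Discretize a waveform into a sampled current trace
#'
#' The train starts with a cathodic onset at t = 0 and repeats at the pulse
#' period. With `align = "midpoint"` sample k holds the waveform value at the
#' midpoint of `[k*dt, (k+1)*dt)` (so a rectangular 0.3 ms phase at dt = 0.01
#' gives exactly 30 samples at the plateau value, and a rectangle-rule sum is
#' the exact integral for rectangular phases). With `align = "grid"` samples
#' sit at `t = k*dt`, which is what the integrator consumes.
#'
#' @param spec a `bgdbs_waveform`.
#' @param dt sample step, ms; must resolve the narrowest phase
#'   (`dt <= cathodic width / 10`).
#' @param duration trace length, ms.
#' @param align `"midpoint"` or `"grid"`.
#' @return a `bgdbs_sampled` list: `dt`, `samples` (uA/cm^2), `pulse_onsets`
#'   (ms), `align`, `spec`.
#' @export
sample_waveform <- function(spec, dt, duration, align = c("midpoint", "grid")) {
  align <- match.arg(align)
  wmin <- min(spec$cathodic$width, spec$anodic$width)
  if (dt > spec$cathodic$width / 10 + 1e-12) {
    stop(sprintf("dt = %g ms too coarse: must satisfy dt <= cathodic width / 10 = %g ms",
                 dt, spec$cathodic$width / 10))
  }
  period <- 1000 / spec$frequency
  nsamp <- if (align == "midpoint") round(duration / dt) else round(duration / dt) + 1
  tt <- if (align == "midpoint") (seq_len(nsamp) - 0.5) * dt else (seq_len(nsamp) - 1) * dt
  u <- tt %% period
  samples <- pulse_value(spec, u)
  onsets <- seq(0, duration - 1e-9, by = period)
  structure(list(dt = dt, samples = samples, pulse_onsets = onsets,
                 align = align, spec = spec),
            class = "bgdbs_sampled")
}

#' Analytic charge of one phase
#'
#' Rectangular: `A*w`; half-sine: `2*A*w/pi`; Gaussian (truncated at the
#' phase edges): `A * sigma * sqrt(2*pi) * erf(w / (2*sqrt(2)*sigma))`.
#'
#' @param phase a `bgdbs_phase`.
#' @return charge, uA*ms/cm^2 (signed).
#' @export
phase_charge <- function(phase) {
  switch(phase$shape,
    rectangular = phase$amplitude * phase$width,
    half_sine = 2 * phase$amplitude * phase$width / pi,
    gaussian = {
      erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
      phase$amplitude * phase$sigma * sqrt(2 * pi) *
        erf(phase$width / (2 * sqrt(2) * phase$sigma))
    })
}

#' Per-pulse charge and imbalance of a waveform
#'
#' The printed presets are not charge balanced (cathodic 60 vs anodic
#' -20 uA*ms/cm^2 for the rectangular pair); this reports both phases and
#' their sum so the imbalance is explicit.
#'
#' @param spec a `bgdbs_waveform`.
#' @return list with `cathodic`, `anodic`, `net` charges (uA*ms/cm^2).
#' @export
waveform_charge <- function(spec) {
  qc <- phase_charge(spec$cathodic)
  qa <- phase_charge(spec$anodic)
  list(cathodic = qc, anodic = qa, net = qc + qa)
}

#' Rescale the anodic phase for exact charge balance
#'
#' Returns a copy of the waveform whose anodic amplitude is rescaled so the
#' per-pulse net charge is zero. Off by default everywhere: the shipped
#' presets reproduce the printed (imbalanced) amplitudes.
#'
#' @param spec a `bgdbs_waveform`.
#' @return a `bgdbs_waveform`.
#' @export
rebalance_anodic <- function(spec) {
  q <- waveform_charge(spec)
  spec$anodic$amplitude <- spec$anodic$amplitude * (-q$cathodic / q$anodic)
  spec$name <- paste0(spec$name, "_balanced")
  spec
}

#' Electrical energy of a sampled waveform over a window
#'
#' Midpoint-rule integral of `I(t)^2 * Z` over the window, in nJ. Unit
#' bookkeeping: uA^2 * kOhm * ms = 1e-12 A^2 * 1e3 Ohm * 1e-3 s = 1e-12 J,
#' i.e. 1e-3 nJ, hence the 1e-3 scale factor.
#'
#' @param sw a `bgdbs_sampled` (midpoint-aligned for exact rectangular
#'   integrals).
#' @param Z impedance, kOhm (constant 1 kOhm in the study setting).
#' @param window integration window `[0, window]`, ms; default the full trace.
#' @return energy, nJ.
#' @export
waveform_energy <- function(sw, Z = 1, window = NULL) {
  nsamp <- length(sw$samples)
  if (is.null(window)) window <- nsamp * sw$dt
  k <- round(window / sw$dt)
  if (k > nsamp) stop("window exceeds the sampled duration")
  sum(sw$samples[seq_len(k)]^2) * Z * sw$dt * 1e-3
}

#' Serialize / deserialize waveform specs
#' @param spec a `bgdbs_waveform`; `path` a file path.
#' @return `waveform_to_json` returns `path` invisibly; `waveform_from_json`
#'   the reconstructed spec.
#' @export
waveform_to_json <- function(spec, path) {
  jsonlite::write_json(unclass_phases(spec), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_phases <- function(spec) {
  s <- unclass(spec)
  s$cathodic <- unclass(s$cathodic)
  s$anodic <- unclass(s$anodic)
  s
}

#' @rdname waveform_to_json
#' @export
waveform_from_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  waveform_spec(
    cathodic = phase_spec(s$cathodic$shape, s$cathodic$amplitude,
                          s$cathodic$width, s$cathodic$sigma),
    delay = s$delay,
    anodic = phase_spec(s$anodic$shape, s$anodic$amplitude, s$anodic$width,
                        s$anodic$sigma),
    frequency = s$frequency, name = s$name
  )
}

#' Export a sampled trace as CSV (t, I)
#' @param sw a `bgdbs_sampled`; `path` a file path.
#' @return `path`, invisibly.
#' @export
sampled_to_csv <- function(sw, path) {
  tt <- if (sw$align == "midpoint") {
    (seq_along(sw$samples) - 0.5) * sw$dt
  } else {
    (seq_along(sw$samples) - 1) * sw$dt
  }
  write.csv(data.frame(t_ms = tt, I_uA = sw$samples), path, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats pnorm
NULL
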