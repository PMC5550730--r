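#' Count DBS pulses that fail to elicit a spike
#'
#' A pulse at onset `o` is a hit if at least one spike falls in
#' `[o, o + period)`; each spike is credited to at most one pulse (the one
#' whose window contains it). The miss count M is the number of pulses with
#' no credited spike.
#'
#' @param pulse_onsets sorted cathodic onset times, ms.
#' @param spikes spike times of one neuron, ms.
#' @param period inter-pulse period (1000/frequency), ms; windows must not
#'   overlap.
#' @return integer miss count.
#' @export
count_misses <- function(pulse_onsets, spikes, period) {
  if (is.unsorted(pulse_onsets)) stop("pulse onsets must be sorted")
  if (length(pulse_onsets) > 1 &&
      any(diff(pulse_onsets) < period - 1e-9)) {
    stop("period mis-set: pulse windows overlap")
  }
  spikes <- sort(as.numeric(spikes))
  misses <- 0L
  si <- 1L
  ns <- length(spikes)
  for (o in pulse_onsets) {
    while (si <= ns && spikes[si] < o) si <- si + 1L
    if (si <= ns && spikes[si] < o + period) {
      si <- si + 1L  # credit this spike to this pulse, once
    } else {
      misses <- misses + 1L
    }
  }
  misses
}

#' Energy-plus-miss cost of a stimulation run
#'
#' `C = integral(I^2 Z dt over W) + 3 * M` nJ: the electrical energy of the
#' waveform over the window plus a fixed 3 nJ penalty per missed pulse.
#'
#' @param waveform a `bgdbs_sampled` (midpoint-aligned).
#' @param M miss count (>= 0; may be a population mean).
#' @param Z impedance, kOhm.
#' @param window integration window, ms; default the full trace.
#' @param penalty_per_miss nJ per miss.
#' @return a `bgdbs_cost` list: `energy`, `M`, `penalty_per_miss`, `C`,
#'   `window`.
#' @export
dbs_cost <- function(waveform, M, Z = 1, window = NULL, penalty_per_miss = 3) {
  stopifnot(M >= 0)
  if (is.null(window)) window <- length(waveform$samples) * waveform$dt
  energy <- waveform_energy(waveform, Z = Z, window = window)
  structure(list(energy = energy, M = M, penalty_per_miss = penalty_per_miss,
                 C = energy + penalty_per_miss * M, window = window),
            class = "bgdbs_cost")
}

#' Plug-in mutual information between two signals
#'
#' Both signals are discretized into `bins` equal-width amplitude bins (over
#' each signal's own range); MI in nats is computed from the joint histogram,
#' with zero-probability cells contributing zero. A constant signal occupies
#' one bin and yields MI = 0.
#'
#' @param y1,y2 equal-length numeric signals.
#' @param bins number of amplitude bins (>= 2).
#' @return a `bgdbs_mi` list: `mi` (nats), `bins`, `joint` (count matrix).
#' @export
mutual_information <- function(y1, y2, bins = 8) {
  stopifnot(length(y1) == length(y2), bins >= 2)
  cut_eq <- function(y) {
    r <- range(y)
    if (r[1] == r[2]) return(rep(1L, length(y)))
    br <- seq(r[1], r[2], length.out = bins + 1)
    pmin(pmax(findInterval(y, br, rightmost.closed = TRUE), 1L), bins)
  }
  i <- cut_eq(y1)
  j <- cut_eq(y2)
  joint <- matrix(0, bins, bins)
  for (k in seq_along(i)) joint[i[k], j[k]] <- joint[i[k], j[k]] + 1
  p <- joint / sum(joint)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  terms <- p * log(p / outer(pi_, pj_))
  mi <- sum(terms[p > 0])
  structure(list(mi = max(mi, 0), bins = bins, joint = joint),
            class = "bgdbs_mi")
}

#' Instantaneous phase via the analytic signal
#'
#' Removes the mean, forms the analytic signal through the FFT construction
#' (negative frequencies zeroed, positive doubled), and returns the
#' four-quadrant phase in `(-pi, pi]`.
#'
#' @param y uniformly sampled signal; must not be constant zero after
#'   mean removal.
#' @return phase series, radians.
#' @export
instantaneous_phase <- function(y) {
  y <- y - mean(y)
  if (all(abs(y) < .Machine$double.eps * 10)) {
    stop("phase undefined: signal is constant (zero after mean removal)")
  }
  n <- length(y)
  Y <- fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(Y * h, inverse = TRUE) / n
  Arg(z)
}

#' Smooth a spike train into a continuous rate signal
#'
#' Convolves the binary spike indicator with a Gaussian kernel (default
#' 10 ms standard deviation), the conversion used before phase extraction.
#'
#' @param spikes spike times, ms.
#' @param duration signal length, ms.
#' @param dt sample step, ms.
#' @param kernel_sd Gaussian kernel width, ms.
#' @return numeric rate-like signal sampled every `dt`.
#' @export
spike_rate_signal <- function(spikes, duration, dt = 1, kernel_sd = 10) {
  tt <- seq(0, duration, by = dt)
  x <- numeric(length(tt))
  idx <- pmin(pmax(round(spikes / dt) + 1, 1), length(tt))
  for (k in idx) x[k] <- x[k] + 1
  half <- ceiling(4 * kernel_sd / dt)
  ku <- seq(-half, half) * dt
  kern <- exp(-ku^2 / (2 * kernel_sd^2))
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(numeric(half), x, numeric(half)), kern,
                           sides = 2))[(half + 1):(half + length(x))]
}

#' Phase-locking value between two signals
#'
#' Modulus of the mean unit phasor of the instantaneous phase difference:
#' 1 for identical signals or any constant phase lag, near 0 for independent
#' phases.
#'
#' @param y_ref,y_test equal-length signals (continuous; smooth spike trains
#'   first with [spike_rate_signal()]).
#' @return a `bgdbs_plv` list: `plv` in `[0, 1]`, `L`, `mode`.
#' @export
plv <- function(y_ref, y_test) {
  if (length(y_ref) != length(y_test)) stop("signals must have equal length")
  p1 <- instantaneous_phase(y_ref)
  p2 <- instantaneous_phase(y_test)
  v <- Mod(mean(exp(1i * (p1 - p2))))
  structure(list(plv = v, L = length(y_ref), mode = "hilbert"),
            class = "bgdbs_plv")
}

#' Per-neuron action-potential count functions
#'
#' Counts spikes of each neuron in consecutive non-overlapping frames
#' (default 15 ms); a partial trailing frame is discarded so no spike is
#' counted twice and all functions share the same length.
#'
#' @param trains list of spike-time vectors (one per neuron), ms.
#' @param duration covered span, ms (>= 2 frames).
#' @param frame frame width, ms.
#' @return integer matrix, neurons x frames.
#' @export
ap_count_functions <- function(trains, duration, frame = 15) {
  stopifnot(frame > 0, duration >= 2 * frame)
  nf <- floor(duration / frame)
  br <- seq(0, nf * frame, by = frame)
  t(vapply(trains, function(s) {
    s <- s[s >= 0 & s < nf * frame]
    as.integer(tabulate(findInterval(s, br, rightmost.closed = FALSE),
                        nbins = nf))
  }, integer(nf)))
}

#' Synchronization level of a population
#'
#' Pearson correlation of every pair of per-neuron frame AP-count functions;
#' SL is the fraction of pairs whose correlation is significant at `alpha`
#' (two-sided t test on L-2 degrees of freedom). The upper triangle excluding
#' the diagonal is evaluated (self-pairs are trivially significant);
#' zero-variance count functions yield undefined correlations and are
#' excluded from both numerator and denominator, with the excluded count
#' reported.
#'
#' @param trains list of spike-time vectors (>= 2 neurons), ms.
#' @param duration covered span, ms.
#' @param frame frame width, ms.
#' @param alpha significance level.
#' @return a `bgdbs_sl` list: `sl`, `n_significant`, `n_total`,
#'   `n_excluded`, `frame`, `alpha`, `cor_matrix`, `p_matrix`, `L`.
#' @export
synchronization_level <- function(trains, duration, frame = 15,
                                  alpha = 0.05) {
  stopifnot(length(trains) >= 2)
  Fm <- ap_count_functions(trains, duration, frame)
  L <- ncol(Fm)
  if (L < 3) stop("need at least 3 frames")
  v <- apply(Fm, 1, sd)
  ok <- v > 0
  if (!any(ok) || sum(ok) < 2) stop("SL undefined: all AP-count functions have zero variance")
  n <- nrow(Fm)
  C <- matrix(NA_real_, n, n)
  P <- matrix(NA_real_, n, n)
  Cok <- cor(t(Fm[ok, , drop = FALSE]))
  rr <- pmin(pmax(Cok, -1 + 1e-15), 1 - 1e-15)
  tt <- rr * sqrt((L - 2) / (1 - rr^2))
  Pok <- 2 * pt(-abs(tt), df = L - 2)
  C[ok, ok] <- Cok
  P[ok, ok] <- Pok
  ut <- upper.tri(C)
  eval_mask <- ut & !is.na(C)
  n_total <- sum(eval_mask)
  n_sig <- sum(P[eval_mask] <= alpha)
  n_excluded <- sum(ut) - n_total
  structure(list(sl = n_sig / n_total, n_significant = n_sig,
                 n_total = n_total, n_excluded = n_excluded, frame = frame,
                 alpha = alpha, cor_matrix = C, p_matrix = P, L = L,
                 diagonal = "excluded"),
            class = "bgdbs_sl")
}

#' @export
print.bgdbs_sl <- function(x, ...) {
  cat(sprintf("SL = %.3f (%d of %d pairs significant at alpha = %g; %d excluded; %d frames of %g ms)\n",
              x$sl, x$n_significant, x$n_total, x$alpha, x$n_excluded, x$L,
              x$frame))
  invisible(x)
}

#' Population firing-rate signal in fixed bins
#'
#' Mean spike count per neuron in consecutive bins; the discretized signal
#' used for the mutual-information comparisons (same 15 ms frames as the
#' synchronization level by default).
#'
#' @param trains list of spike-time vectors, ms.
#' @param duration covered span, ms.
#' @param bin bin width, ms.
#' @return numeric vector of mean counts per bin.
#' @export
population_rate_signal <- function(trains, duration, bin = 15) {
  colMeans(ap_count_functions(trains, duration, frame = bin))
}

#' Normalized energy threshold over a delay x frequency grid
#'
#' For each (delay, frequency) cell, bisects the cathodic amplitude (anodic
#' amplitude held at 1/10 of cathodic, widths at the 1:3.3 cathodic:anodic
#' ratio) for the minimal stimulation energy at which at least `criterion`
#' of the DBS pulses elicit a spike from the quiescent network-loaded STN
#' cell, then min-max
#' normalizes the grid to `[0, 1]`. Cells where the criterion is unreachable
#' at the amplitude cap are flagged `NA` and excluded from normalization.
#'
#' @param shape phase shape (`"rectangular"`, `"half_sine"`, `"gaussian"`).
#' @param delays delay axis, ms.
#' @param freqs frequency axis, Hz.
#' @param criterion required fraction of pulses eliciting a spike.
#' @param n_pulses pulses per trial.
#' @param amp_max amplitude cap, uA/cm^2.
#' @param tol_amp bisection resolution, uA/cm^2.
#' @param cathodic_width cathodic width, ms.
#' @param dt integration step, ms.
#' @return a `bgdbs_net_grid` list: `raw` and `net` matrices
#'   (delays x freqs), axes, and the failure mask.
#' @export
net_grid <- function(shape = "gaussian", delays = seq(0, 0.5, by = 0.05),
                     freqs = seq(30, 180, by = 10), criterion = 0.5,
                     n_pulses = 8, amp_max = 600, tol_amp = 2,
                     cathodic_width = 0.3, dt = 0.01) {
  stopifnot(length(delays) > 0, length(freqs) > 0, criterion > 0)
  raw <- matrix(NA_real_, length(delays), length(freqs),
                dimnames = list(paste0("DL", delays), paste0("Fs", freqs)))
  for (di in seq_along(delays)) {
    for (fi in seq_along(freqs)) {
      fr <- freqs[fi]
      period <- 1000 / fr
      if (cathodic_width * 4.3 + delays[di] >= period) next
      success <- function(amp) {
        tr <- stim_trial(shape, amp, delays[di], fr, n_pulses,
                         cathodic_width, dt)
        tr$frac >= criterion
      }
      if (!success(amp_max)) next
      lo <- 0; hi <- amp_max
      while (hi - lo > tol_amp) {
        mid <- (lo + hi) / 2
        if (success(mid)) hi <- mid else lo <- mid
      }
      tr <- stim_trial(shape, hi, delays[di], fr, n_pulses, cathodic_width, dt)
      raw[di, fi] <- tr$energy
    }
  }
  rng <- range(raw, na.rm = TRUE)
  net <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
  structure(list(raw = raw, net = net, delays = delays, freqs = freqs,
                 criterion = criterion, failed = is.na(raw), shape = shape),
            class = "bgdbs_net_grid")
}

# one stimulation trial on the quiescent network-loaded STN cell: n_pulses
# of the given family at nominal amplitude amp (uA, scaled by the electrode
# coupling); returns the fraction of pulses eliciting a spike and the nominal
# train energy over the window.
stim_trial <- function(shape, amp, delay, frequency, n_pulses,
                       cathodic_width = 0.3, dt = 0.01) {
  spec <- waveform_spec(
    cathodic = phase_spec(shape, amplitude = amp, width = cathodic_width),
    delay = delay,
    anodic = phase_spec(shape, amplitude = -amp / 10,
                        width = 3.3 * cathodic_width),
    frequency = frequency
  )
  period <- 1000 / frequency
  duration <- n_pulses * period
  swm <- sample_waveform(spec, dt = min(dt, 0.01), duration = duration,
                         align = "midpoint")
  swg <- sample_waveform(spec, dt = dt / 2, duration = duration,
                         align = "grid")
  bias <- cell_params("STN")$bias$pd
  init <- loaded_stn_rest(bias)
  res <- run_single_cell("STN", I_inj = swg$samples * dbs_coupling(),
                         dt_inj = dt / 2, duration = duration, dt = dt,
                         init = init, bias = bias, g_load = 1.0,
                         E_load = -85, record_every = 5L)
  hits <- vapply(swm$pulse_onsets, function(o) {
    any(res$spikes >= o & res$spikes < o + period)
  }, logical(1))
  list(frac = mean(hits), energy = waveform_energy(swm),
       spikes = res$spikes, onsets = swm$pulse_onsets)
}

#' Miss statistics of a simulation under DBS
#'
#' Per-neuron miss counts over the analysis window for the first DBS target
#' population, and their mean (the M entering the cost function).
#'
#' @param result a `bgdbs_result` from a run with DBS.
#' @param population population to assess; default the first DBS target.
#' @return list with `per_neuron` counts, `mean`, `n_pulses`.
#' @export
miss_stats <- function(result, population = NULL) {
  cfg <- result$config
  if (is.null(cfg$dbs)) stop("simulation was run without DBS")
  if (is.null(population)) population <- cfg$dbs_targets[1]
  period <- 1000 / cfg$dbs$frequency
  onsets <- result$dbs_onsets
  onsets <- onsets[onsets + period <= result$window + 1e-9]
  per <- vapply(result$spikes[[population]], function(s) {
    count_misses(onsets, s, period)
  }, integer(1))
  list(per_neuron = per, mean = mean(per), n_pulses = length(onsets))
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps so the phase advances continuously; used when
#' estimating instantaneous frequency from [instantaneous_phase()].
#'
#' @param p phase series, radians.
#' @return unwrapped series.
#' @export
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
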