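test_that("presets carry the printed amplitudes, widths, delays and frequency", {
  for (nm in preset_names()) {
    w <- make_preset(nm)
    expect_equal(w$cathodic$amplitude, 200)
    expect_equal(w$cathodic$width, 0.3)
    expect_equal(w$anodic$amplitude, -20)
    expect_equal(w$anodic$width, 1)
    expect_equal(w$frequency, 130)
    expect_equal(w$cathodic$width / w$anodic$width, 0.3)  # the 1:3.3 ratio
  }
  expect_equal(make_preset("GDG")$delay, 0.7)
  expect_equal(make_preset("SDS")$delay, 0.7)
  expect_equal(make_preset("PDP")$delay, 0.7)
  expect_equal(make_preset("Pulse")$delay, 0)
  expect_equal(make_preset("Gaussian")$delay, 0)
  expect_equal(make_preset("Pulse")$cathodic$shape, "rectangular")
  expect_equal(make_preset("SDS")$cathodic$shape, "half_sine")
  expect_equal(make_preset("GDG")$cathodic$shape, "gaussian")
  expect_error(make_preset("Triangle"))
})

test_that("a pulse must fit within its period", {
  expect_error(waveform_spec(phase_spec("rectangular", 200, 4), 2,
                             phase_spec("rectangular", -20, 4), frequency = 130),
               "period")
})

test_that("sampling resolves phases exactly and keeps the delay at zero", {
  sw <- sample_waveform(make_preset("PDP"), dt = 0.01, duration = 1000 / 130)
  # rectangular 0.3 ms cathodic phase at dt = 0.01 -> exactly 30 samples of 200
  expect_equal(sum(sw$samples == 200), 30)
  tt <- (seq_along(sw$samples) - 0.5) * sw$dt
  in_delay <- tt > 0.3 & tt < 1.0
  expect_true(all(sw$samples[in_delay] == 0))
  # anodic plateau of -20 over 1 ms
  expect_equal(sum(sw$samples == -20), 100)
  expect_error(sample_waveform(make_preset("PDP"), dt = 0.05, duration = 10),
               "dt")
})

test_that("gaussian phase peaks at the stated amplitude at the phase midpoint", {
  sw <- sample_waveform(make_preset("Gaussian"), dt = 0.01, duration = 2)
  expect_equal(max(sw$samples), 200, tolerance = 0.005)
})

test_that("pulse onsets are spaced by the period starting at zero", {
  sw <- sample_waveform(make_preset("GDG"), dt = 0.01, duration = 100)
  expect_equal(sw$pulse_onsets[1], 0)
  expect_equal(unique(round(diff(sw$pulse_onsets), 9)), round(1000 / 130, 9))
})

test_that("analytic phase charges match closed forms and quadrature", {
  expect_equal(phase_charge(phase_spec("rectangular", 200, 0.3)), 60)
  expect_equal(phase_charge(phase_spec("rectangular", -20, 1)), -20)
  expect_equal(phase_charge(phase_spec("half_sine", 200, 0.3)),
               2 * 200 * 0.3 / pi)
  # numeric integration of the sampled trace agrees within 0.1 %
  for (shape in c("half_sine", "gaussian")) {
    ph <- phase_spec(shape, 150, 0.4)
    spec <- waveform_spec(ph, 0, phase_spec("rectangular", -1, 0.1),
                          frequency = 100)
    sw <- sample_waveform(spec, dt = 0.001, duration = 0.4)
    expect_equal(sum(sw$samples) * 0.001, phase_charge(ph), tolerance = 1e-3)
  }
})

test_that("train charge is additive over pulses", {
  spec <- make_preset("PDP")
  q1 <- waveform_charge(spec)
  sw <- sample_waveform(spec, dt = 0.005, duration = 10 * 1000 / 130)
  expect_equal(sum(sw$samples) * 0.005, 10 * q1$net, tolerance = 1e-3)
})

test_that("single-pulse energies match the I^2*Z*t closed form", {
  sw <- sample_waveform(make_preset("Pulse"), dt = 0.005, duration = 1000 / 130)
  # 200 uA x 0.3 ms + (-20 uA) x 1 ms at 1 kOhm -> 12 + 0.4 nJ
  expect_equal(waveform_energy(sw), 12.4, tolerance = 1e-10)
  # the interphase delay contributes nothing
  swd <- sample_waveform(make_preset("PDP"), dt = 0.005, duration = 1000 / 130)
  expect_equal(waveform_energy(swd), 12.4, tolerance = 1e-10)
})

test_that("per-pulse energy orders gaussian < half-sine < rectangular at equal peak", {
  e <- vapply(c("Gaussian", "Sinusoid", "Pulse"), function(nm) {
    waveform_energy(sample_waveform(make_preset(nm), dt = 0.005,
                                    duration = 1000 / 130))
  }, numeric(1))
  expect_true(e[["Gaussian"]] < e[["Sinusoid"]])
  expect_true(e[["Sinusoid"]] < e[["Pulse"]])
})

test_that("energy over a window scales with the pulse count", {
  spec <- make_preset("GDG")
  period <- 1000 / 130
  e1 <- waveform_energy(sample_waveform(spec, 0.005, period))
  e10 <- waveform_energy(sample_waveform(spec, 0.005, 10 * period))
  expect_equal(e10, 10 * e1, tolerance = 0.01)
})

test_that("rebalancing zeroes the net charge; presets are imbalanced as printed", {
  spec <- make_preset("Pulse")
  expect_equal(waveform_charge(spec)$net, 40)  # 60 - 20, as printed
  bal <- rebalance_anodic(spec)
  expect_equal(waveform_charge(bal)$net, 0, tolerance = 1e-12)
})

test_that("waveform specs round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  waveform_to_json(make_preset("SDS"), f)
  back <- waveform_from_json(f)
  expect_equal(back$cathodic$amplitude, 200)
  expect_equal(back$delay, 0.7)
  expect_equal(back$cathodic$shape, "half_sine")
  unlink(f)
})
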