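---
title: "Basal ganglia network simulation and DBS waveform evaluation with bgdbs"
author: "bgdbs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basal ganglia network simulation and DBS waveform evaluation with bgdbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgdbs)
```

## The model

`bgdbs` simulates a four-population basal ganglia circuit — thalamus (TH),
subthalamic nucleus (STN), external and internal globus pallidus (GPe, GPi) —
with single-compartment conductance-based neurons of the Rubin–Terman /
So et al. family (Rubin & Terman 2004, *J Comput Neurosci*; So et al. 2012,
*J Comput Neurosci*). Each neuron obeys

$$C_m \frac{dV}{dt} = -\sum_{\mathrm{ion}} g_{\mathrm{ion}}\,
m_\infty^M h^N (V - E_{\mathrm{ion}}) + I_{\mathrm{syn}} + I_{\mathrm{ext}} +
I_{\mathrm{bias}},$$

with leak, sodium, potassium, high-threshold calcium and low-threshold
T-type currents (plus the calcium-dependent after-hyperpolarization current
that the source models tie to the T/Ca calcium influx). Conductances,
reversal potentials and capacitances are shipped as a versioned JSON table
(`inst/extdata/cell_params.json`); the gating steady-state curves and time
constants are the source-model forms, mirrored identically in R
(`gating_kinetics()`) and in the compiled integrator, with a unit test
holding the two implementations together.

Condition is encoded entirely in the bias currents: healthy
(STN 29, GPe 20, GPi 22 µA/cm²) versus Parkinsonian
(20, 8, 12 µA/cm²). TH receives no bias; it is driven by a stochastic
sensorimotor-cortex (SMC) pulse train and inhibited by GPi.

Two identification choices deserve emphasis, because the circuit's
population-level phenotype depends on them:

* **T-current reversal.** The T current uses the calcium reversal
  (140 mV for STN, 120 mV for GPe/GPi), as in the source models. With a
  0 mV reversal the rebound-burst mechanism collapses and the Parkinsonian
  network fails to synchronize. TH keeps the 0 mV thalamic T reversal.
* **Intra-pallidal coupling sign.** The GPe→GPe and GPe→GPi terms enter the
  membrane equation with a positive sign (`gpe_term_sign` in the parameter
  file), i.e. as activity-dependent positive feedback within the pallidum,
  while GPe→STN and GPi→TH are conventional hyperpolarizing GABAergic
  currents. This configuration is what produces the defining regime of the
  model: an asynchronous healthy state and a strongly synchronized
  Parkinsonian state of GPi (the acceptance suite measures both). Setting
  `gpe_term_sign = -1` gives conventional inhibition everywhere and an
  asynchronous network in both conditions.

## Network wiring

Fan-in follows the circuit's connection table: each GPe neuron receives
2 STN + 2 GPe afferents, each GPi 2 STN + 2 GPe, each STN 2 GPe, each TH
1 GPi. `build_topology()` assigns partners either with a deterministic
wrap-around rule (neuron *i* listens to *i*, *i*+1; the default, exactly
reproducible) or uniformly at random under a seed. GPe self-connections are
excluded. Synaptic gates follow first-order kinetics
$\dot s = \alpha H(V_{pre})(1-s) - \beta s$ with a spike-shaped activation
$H(V) = 1/(1+e^{-(V+20)/2})$; excitatory gates rise fast and decay in 1 ms
($\alpha = 5, \beta = 1$), inhibitory gates decay in 12.5 ms
($\alpha = 2, \beta = 0.08$).

## Stimulation waveforms

A DBS pulse is *cathodic phase → interphase delay → anodic phase*, repeated
at the stimulation frequency. Phases are rectangular, half-sine, or
Gaussian; `amplitude` always means the **peak** current, and the Gaussian
bell uses $\sigma = w/6$ so its ±3σ support spans the phase width (both
choices make the shapes comparable at the printed peak and give the
energy ordering Gaussian < half-sine < rectangular at equal peak). The six
presets share a 200 µA × 0.3 ms cathodic phase, a −20 µA × 1 ms anodic
phase (the 1:3.3 width ratio), and 130 Hz; the delay variants (PDP, SDS,
GDG) insert a 0.7 ms interphase delay. Note that the printed preset phases
integrate to a 3:1 cathodic:anodic charge ratio — they are *not* charge
balanced; `waveform_charge()` reports the imbalance and
`rebalance_anodic()` provides an exactly balanced variant, off by default.

Nominal amplitudes in µA are injected as µA/cm² on the unit-area
compartment (coupling efficiency 1, the dimensional reading consistent with
every other current in the membrane equations). A `dbs_coupling` knob
scales this transfer: reducing it to ≈ 0.08 reproduces the published
interphase-gap threshold anchor for rectangular pulses (a ~200 µA threshold
reached only at delays ≳ 0.65 ms, cf. Hofmann et al. 2011), but at that
coupling none of the 200 µA presets can drive the network, so unit coupling
is the default. The two regimes cannot be reconciled by any single
coupling value; this is a genuine tension in the literature values the
presets come from, and the package exposes the knob rather than hiding the
choice.

## Integration

A fixed-step RK4 scheme (default dt = 0.01 ms; forward Euler available)
advances all membrane, gating and synaptic state. Gates are clamped to
[0, 1] after each step and clamping beyond 1e−6 is counted and reported
(`clamp_events`; zero in routine runs). Any |V| > 200 mV aborts with the
time and neuron index. Spikes are strict upward crossings of −20 mV with a
2 ms refractory window. Halving dt changes population rates by < 5 % and
single-cell spike counts by ≤ 1 (tested).

The SMC drive is a per-neuron seeded pulse train: 3 µA/cm², 5 ms pulses
with Gaussian inter-pulse intervals of mean 1000/14 ms and CV 0.2,
intervals below the pulse width redrawn. Initial conditions draw each
membrane potential uniformly from [−70, −50] mV with gates at their
steady state — the network's only other randomness. Everything is
reproducible bit-for-bit from `(config, seed, dt)`.

## Evaluation metrics

* **Cost** `C = ∫ I²Z dt + 3·M` (nJ, Z = 1 kΩ): waveform energy over a
  common window plus a 3 nJ penalty per miss. A *miss* is a DBS pulse with
  no spike of the target neuron in [onset, onset + period); the package
  counts misses per targeted STN neuron and averages. The default window is
  40 pulses (≈ 308 ms at 130 Hz), chosen because the rectangular preset's
  published total energy is consistent with ≈ 40 pulses of its 12.4 nJ
  per-pulse energy; all presets are compared over the same window.
* **Mutual information**: plug-in histogram MI in nats between two signals
  discretized into 8 equal-width bins (population rate signals in the same
  15 ms frames as the SL, by default).
* **Phase-locking value**: spike trains are smoothed with a 10 ms Gaussian
  kernel, mean-removed, passed through the FFT analytic-signal
  construction, and the modulus of the mean unit phasor of the phase
  difference is reported.
* **Synchronization level (SL)**: per-neuron spike counts in
  non-overlapping 15 ms frames, Pearson correlations over all neuron pairs
  (upper triangle, diagonal excluded — self-pairs are trivially
  significant), two-sided t-test on L−2 degrees of freedom, and
  SL = (significant pairs at α = 0.05)/(evaluated pairs). Zero-variance
  count functions are excluded from numerator and denominator and the
  exclusion count is reported. Under independent trains SL estimates the
  type-I error rate ≈ α (tested).
* **Normalized energy threshold (NET)**: over a delay × frequency grid,
  bisection finds the minimal stimulation energy at which ≥ 50 % of pulses
  elicit spikes from a quiescent network-loaded STN cell; the grid is
  min–max normalized to [0, 1] per panel, with unreachable cells flagged
  and excluded.

## The delay-threshold experiment

The strength–interphase-delay experiment measures, per delay, the minimal
cathodic amplitude whose single pulse elicits a spike (10:1
cathodic:anodic peak ratio, 3.3:1 anodic:cathodic width ratio, 1 µA
bisection). The target is a *quiescent* STN cell: Parkinsonian bias with a
static 1.0 mS/cm² inhibitory conductance load to −85 mV, the mean load of
its two pallidal afferents near saturation. An isolated STN cell at the
healthy bias is a ~25 Hz pacemaker, which makes "eliciting a spike"
phase-dependent and the threshold ill-defined; the loaded cell makes the
measurement well-posed. Minimal amplitude is non-increasing in the delay
(tested), reflecting the interphase-gap effect: the gap lets the cathodic
depolarization develop before the anodic phase reverses it.

## Desk-scale study conditions

The headline comparisons run 100 neurons per population, a 1 s analysis
window after a 0.5 s discarded transient, 3 seeds, DBS on STN at 130 Hz —
sizes at which one condition simulates in ~15 s on one CPU and the whole
acceptance battery in minutes, while rate and SL estimates are stable
across seeds. The wiring scales to 1000/population unchanged; the per-pulse
energy term is independent of network size by construction (tested), and
miss statistics are per-neuron means, so they do not grow with the
population.

## What the generator does and does not emulate

The synthetic SMC train reproduces the stated rate (14 Hz), variability
(CV 0.2) and pulse shape of cortical drive, not any temporal structure of
real movement-related cortical activity. The network has no electrode
geometry, no distance-dependent stimulation (every targeted neuron receives
the identical current density), no conduction delays, no plasticity, and no
intrinsic membrane noise — all variability across neurons comes from
initial conditions, wiring and the SMC drive. Passing tests therefore
certify the model's internal, deterministic phenomenology, not quantitative
agreement with recordings.

## Known limitations

* The preset family sits far above the model's elicitation threshold at
  unit coupling (thresholds 16–41 µA/cm² for 0.3 ms phases), so the
  rectangular and half-sine presets follow 1:1 at 130 Hz and their delay
  variants change misses only marginally; the delay advantage materializes
  near threshold (reduced `dbs_coupling`), where in turn the presets cease
  to drive the network. Both regimes are one parameter away.
* At a 10:1 peak-amplitude ratio the three waveform families' thresholds
  differ by up to 2.3×, so a single 200 µA reference line cannot intersect
  all three delay-threshold curves; only amplitude-ordering and
  monotonicity claims are family-independent.
* The intra-pallidal positive-feedback reading drives pallidal rates above
  typical physiological values (GPe ≈ 100–130 Hz); the synchronization
  *orderings* across conditions, not absolute rates, are the quantities the
  package is designed to reproduce.

## A minimal session

```{r, eval = FALSE}
library(bgdbs)

pd <- run_condition("pd", n_per_pop = 100, seed = 1)
gdg <- run_condition("GDG", n_per_pop = 100, seed = 1)

synchronization_level(pd$spikes$GPi, pd$window)
cost_from_result(gdg)

delay_threshold_curves(c("GDG", "SDS", "PDP"))
```
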