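---
title: "Burst metrics, eEPSC analysis and the trapping-block model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst metrics, eEPSC analysis and the trapping-block model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habtrap)
```

# Scope

`habtrap` re-implements, as tested library code, the computational analyses
used to study how a single dose of ketamine keeps suppressing lateral
habenula (LHb) NMDA-receptor currents and burst firing long after the drug
has been eliminated from the brain:

1. inter-spike-interval **burst detection** and the two burst metrics;
2. binned **z-score classification** of in vivo unit responses to a drug
   injection, with the basal 2-Hz split;
3. **evoked-EPSC component analysis** (AMPAR peak at −70 mV, NMDAR
   amplitude 35 ms after stimulation at +40 mV, NMDA/AMPA ratios,
   input–output curves, washout/maximal-blockade/recovery statistics);
4. **mono-exponential pharmacokinetics** (elimination half-life);
5. a **four-state kinetic model** of use-dependent open-channel block with
   trapping, driven by stimulation protocols.

No recorded data ship with the package; a synthetic-data module generates
inputs with the statistical structure each analysis assumes, so every
stage is testable end to end. The `analysis/` scripts run the stages as a
narrative workflow and write their tables under `results/`.

# Burst detection

A burst is a cluster of spikes that *opens* at an inter-spike interval
(ISI) of at most 20 ms and *extends* while ISIs stay at or below 50 ms;
bursts closer together than 50 ms are merged and bursts with fewer than
2 spikes discarded (`burst_params()`). Two readings of the published
criteria are possible and we pin them explicitly:

* "ending with a minimal inter-spike interval of 50 ms" is read as: the
  burst terminates at the first ISI *exceeding* 50 ms, i.e. 50 ms is the
  largest ISI allowed to remain inside a burst. This matches the
  max-interval convention of the commercial spike-train packages and is
  the only reading under which two-spike bursts can exist.
* "minimal intra-burst interval ... 50 ms" is read as the minimal
  *inter-burst* separation (bursts closer than that are merged). The
  alternative reading — a minimum burst duration — is selectable by
  setting the parameters yourself, but is not the default. With the
  default parameters merging can never actually trigger, because a burst
  only ends at an ISI longer than the merge threshold.

The scan is greedy left-to-right with earliest-onset priority; spike times
are strictly increasing so ties cannot arise. Spikes live in the half-open
window `[t_start, t_stop)` and ISIs are computed in milliseconds without
rounding. The test suite checks the detector against an independently
written brute-force scan on 1,200 random trains, including randomized
criteria.

The two metrics follow their definitions directly: bursting spike
frequency = bursting spikes per second of window; bursts per minute =
bursts per minute of window (`burst_metrics()`).

**Neuron typing.** The three-way silent/tonic/burst typing of
spontaneously active neurons is reported in the source experiments without
numeric thresholds, so `typing_criteria()` exposes documented assumptions:
silent below 0.1 Hz mean rate, burst at ≥ 1 detected burst/min, tonic
otherwise. Published type proportions therefore cannot be reproduced
exactly, only qualitatively.

# Unit-response z-score

For each unit, the binned metric (bursting spike frequency by default) is
computed in contiguous 100-s bins. With `xbar` the mean over the
post-injection window (20–30 min after injection), and `mu`, `sigma` the
mean and standard deviation over the 10-min pre-injection baseline,

$$ z = (\bar{x} - \mu) / \sigma, $$

and a unit is *inhibited* when `z ≤ −1.67`, *excited* when `z ≥ 1.67`
(the two-tailed *P* < 0.05 point of the standard normal), *unchanged*
otherwise. Choices the published description leaves open:

* `sigma` uses the sample (n−1) denominator — unbiased at the 6 baseline
  bins a 10-min baseline provides;
* bins not fully covered by the recording are dropped, not padded;
* a zero baseline `sigma` raises a degenerate-baseline condition rather
  than silently producing `z = 0` or `Inf`;
* a unit exactly at the 2-Hz basal cutoff goes to the low group
  ("larger than 2 Hz" is strict).

Because the baseline statistics come from only six bins, the null
distribution of `z` is t-like rather than normal, and `xbar` itself
averages six bins, so the per-tail false-positive rate under the null is
well below the nominal 5%; the Monte-Carlo test over 1,000 simulated
null units checks the ≤ 5% bound per tail.

# eEPSC measurement

Amplitudes are magnitudes of baseline-subtracted current (inward currents
are negative in raw traces; published values are positive pA). The
baseline is the mean current in the 10 ms before stimulation onset; the
AMPAR peak is searched in a 0–100 ms post-stimulus window; the NMDAR
read-out is the value 35 ms after stimulation onset at +40 mV, where the
fast AMPAR component (decay ≤ 5 ms) has died away to < 1% of its peak.
The 35-ms value uses nearest-sample lookup at sampling rates ≥ 10 kHz and
linear interpolation below. Neither the peak window nor the baseline
interval is stated in the source; both are exposed arguments.

Washout series are normalized to the mean of the 5-min baseline epoch
(idempotent by construction). Blockade is evaluated in 10-min bins tiling
from the *wash-in onset*; the maximal bin is the maximal blockade (it may
occur after the wash-in ends — that is the trapping signature), the
"50–60 min" bin supplies the late blockade, and recovery is their
difference. We count the 50–60 min window from wash-in onset because the
published schedule (10-min wash-in plus 50 min of washout, reported at
50–60 min) only adds up on that clock; `clock = "washout"` selects the
alternative. Cells with baseline NMDAR-eEPSCs under 10 pA are excluded
from washout analysis in the workflow scripts, mirroring the recording
practice. Maximal-blockade ties resolve to the earliest bin.

# Pharmacokinetics

`fit_monoexp()` fits `ln C` against time by least squares; the half-life
is `ln 2 / |slope|`, exact on noiseless mono-exponential input.
Non-positive concentrations are dropped with a warning when they are at
most 20% of the points and are an error otherwise. The measured brain
concentration curve is not mono-exponential from its peak, so for driving
the kinetic simulator a tabulated profile can be used directly as a
piecewise-linear forcing function (`conc_fun_from_profile()`) instead of
being forced through a parametric fit.

# The trapping-block model

Four states: closed-unbound (C), open-unbound (O), open-blocked (OB) and
closed-blocked (CB, trapped). The blocker enters and leaves the pore only
while the channel is open; closure around a bound blocker traps it, and
the only exit from CB is re-opening. There is no unbinding from CB — with
no channel opening the blocked fraction is *exactly* conserved, which is
the trapping hypothesis as a model property (and a unit test).

```
        r_open            kon·conc
   C  <-------->  O  <------------->  OB
        alpha             koff              alpha  |  r_open
                                      CB  <--------+-------->  OB
```

Occupancies evolve under a piecewise-constant-rate master equation.
Within each regime the propagator is the matrix exponential of the
generator, and regime boundaries (agonist events, depolarization windows,
concentration steps) are stepped exactly, so 2-ms events are never
aliased. An explicit-Euler mode exists with a hard stability check; the
tests compare the exact stepping against an independent fine-step
Runge–Kutta oracle to 10⁻⁶.

**Parameters (all configurable; a literature-anchored calibration, not a
fit):**

| parameter | default | anchor |
|---|---|---|
| `Kd` | 0.8 μM | reported ketamine–NMDAR dissociation constant |
| `koff0` | ln 2 / 9 s⁻¹ | mid-point of the reported 5–13 s in-solution dissociation time |
| `kon` | `koff0 / Kd` | definition of `Kd` |
| `alpha` (closing = trapping rate) | 200 s⁻¹ | open duration < 10 ms (5-ms mean) |
| `beta_drive` (opening during glutamate) | 500 s⁻¹ | a 1–2 ms synaptic glutamate exposure opens with probability ≈ 1 − e⁻¹ |
| `Po_spont` | 0.04 | intrinsic open probability of synaptic NMDARs without stimulation |
| `spont_event_rate` | 0.01 s⁻¹ | rare spontaneous glutamate exposures; `Po_spont × spont_event_rate` is the resting opening rate |
| `depol_factor` (on `koff` during depolarization) | 3 | direction only ("accelerate release by depolarization"); magnitude unconstrained |
| `mg_open_scale` | 1 (Mg-free) | scalar opening restriction under physiological Mg²⁺ (0.2 in the workflow); depolarization lifts it |

Memantine differs from ketamine by a single parameter: a 20-fold faster
off-rate at the same `Kd` ("similar affinity but faster off-rate"); an
optional `cb_escape` rate exists for sensitivity analysis (default 0).

**What the model reproduces.** At steady state under sustained agonist the
blocked fraction of open receptors is the binding isotherm
`conc/(conc + Kd)` — half-occupancy at `Kd` (an acceptance-level check,
solved numerically, matching the closed form to 10⁻⁹). From this follow
the dynamic-equilibrium predictions: openings at ambient concentrations
below `Kd` produce net unbinding, above `Kd` net binding (the 0.23 μM vs
6 μM bidirectional property). Washout simulations show deep residual
blockade for the ketamine preset and fast recovery for the memantine
preset; the kick-off protocol (2 sessions × 5 pairings × 3 events,
30 presynaptic events, with co-extensive depolarization) strictly lowers
residual blockade while presynaptic stimulation alone barely does; and
with only spontaneous openings the blocked fraction decays orders of
magnitude slower than the in-solution dissociation time. The apparent
IC50 of a finite 10-min application under restricted opening
(`mg_open_scale = 0.2`, brief events at 2 Hz) lands several fold above
`Kd`, near the reported ~5 μM under magnesium, while the unrestricted
equilibrium curve collapses onto `Kd` exactly.

**What it does not.** Rates for trapping and closing are nowhere
published; magnitudes of the kick-off recovery and of the IC50 shift
depend on the calibration above (particularly `depol_factor` and the
event rate), so those comparisons are directional, not quantitative. The
model is mean-field (a Gillespie mode exists for single-channel
illustration only), has no Woodhull voltage dependence, no Mg²⁺ flicker
kinetics, no subunit composition, and no rebinding/diffusion pool. How a
40-Hz optogenetic stimulus maps onto per-synapse glutamate-exposure rate
is unknown; the bidirectional property is asserted for the model's own
event-rate parameter.

# Synthetic data: what it emulates, what it does not

* **Tonic trains** are refractory-thinned Poisson processes (2-ms
  refractory period; the published sorting criteria exclude ISIs < 1 ms,
  so 2 ms is conservative).
* **Burst trains** place Poisson burst onsets and fill each burst with a
  geometric ISI progression `isi0 · growth^k` — the simplest monotone
  model of "initially high, progressively declining intra-burst
  frequency"; no quantitative intra-burst ISI distribution is published,
  so these defaults (8 ms, ratio 1.3, 5 spikes) are placeholders, not
  fitted values. Background spikes are kept more than 60 ms from bursts
  and from each other so that burst membership is unambiguous by
  construction; real background firing is not so polite.
* **Session cohorts** draw basal bursting spike frequency from a two-mode
  log-normal mixture (modes 0.5 and 4 Hz, 27% high, log-SD 0.25) to
  emulate the observed bimodal distribution with roughly 27% of units
  above 2 Hz; "inhibited" units have their burst rate multiplied by a
  constant factor from the injection time. Real drug effects ramp with
  absorption kinetics rather than switching instantaneously.
* **eEPSC sweeps** are sums of two difference-of-exponential components
  (AMPA rise 0.5 / decay 3 ms; NMDA rise 5 / decay 80 ms — assumptions,
  LHb-specific constants are not reported) plus Gaussian noise; under
  physiological Mg²⁺ the NMDAR component at −70 mV is multiplied by a
  suppression factor (0 by default, 1 in the no-added-Mg²⁺ mode). No
  stimulus artifacts, series-resistance errors or rundown are simulated.
* **Concentration series** are mono-exponential with multiplicative
  log-normal noise; **washout series** take their dynamics from the
  trapping model plus Gaussian measurement noise.

Every generator draws through a single integer seed (restoring the
caller's RNG state) and is bit-identical on repeated calls; child seeds
are derived arithmetically so modules can be tested independently.
Passing tests on these data demonstrate that the analysis code implements
its definitions and recovers designed parameters — not that the
generators' simplifications hold in recorded tissue.

# Numerical choices and problem sizes

Tolerances: probability conservation to 10⁻⁹; equilibrium solver vs
closed form to 10⁻⁹; integrator vs oracle to 10⁻⁶; OLS regression vs the
reference fit to 10⁻⁶; exact half-life recovery on noiseless input to
10⁻⁶. Degenerate inputs raise typed conditions
(`habtrap_degenerate_baseline`, `habtrap_undefined_blockade`,
`habtrap_stability_error`, ...) rather than returning silent zeros.

The shipped workflow and tests use cohorts of 97 in vivo units (1,000 for
the null false-positive check), 12–16 eEPSC neurons, 65-min washout
simulations at 10-s pulse resolution, and 3-min 40-Hz trains — sizes at
which the full suite completes in about a minute on a laptop while
keeping Monte-Carlo tolerances (3 standard errors) meaningful.
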