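---
title: "Methods: models, defaults and design choices in duovolt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in duovolt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duovolt)
```

# Scope

`duovolt` analyzes simultaneous two-photon voltage (slow, negative-going,
soma-targeted GEVI) and calcium imaging of cortical layer-2/3 populations,
and ships a synthetic-data generator rich enough that every analysis stage
can be verified against known ground truth. This vignette records the
models, the tunable parameters with their units and defaults, what the
generator does and does not emulate, and the design choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The voltage-indicator forward model

Fluorescence is a static Boltzmann function of membrane potential followed
by linear kinetics and photobleaching:

$$F_\infty(V) = B + \frac{\Delta F_{max}}
  {1 + \exp\{-p\,(V - V_{1/2})/k\}}, \qquad p \in \{-1, +1\}$$

with `polarity` $p = -1$ (fluorescence falls on depolarization, the
ArcLight convention) the sigmoid is non-increasing in $V$ over the whole
range — a property the tests assert. The instantaneous value is filtered by
a two-exponential kernel (`frac_fast` = 0.7 at `tau_fast` = 60 ms, the
remainder at `tau_slow` = 300 ms) implemented as exact one-pole recursions,
so a voltage step produces exactly the double-exponential rise that the
calibration module fits; the fitted fast component returns the configured
60 ms to machine precision on noiseless input. Photobleaching multiplies
$\exp(-t/\tau_{bleach})$ (`Inf` disables it; scenario default 300 s).

**Parameter defaults and why.** The F–V curve of the soma-targeted variant
is published only as a plot, never as a parameter table, so defaults were
*derived*, not copied: with $V_{1/2} = -30$ mV, $k = 25$ mV,
$\Delta F_{max} = 0.45$ and baseline 1, the local slope at the resting
potential of −68.5 mV is −0.191 %ΔF/F per mV — the value back-solved from
the published detection-limit arithmetic (baseline mean −0.28 %ΔF/F, SD
0.88 %ΔF/F, limit 15.3 mV implies slope ≈ −0.1908 %/mV). The parent
("MT") preset differs only in $V_{1/2} = -10$ mV, which reproduces the
qualitative ordering: the soma-targeted variant has the more negative
midpoint and responds roughly twice as strongly to a 20 mV step from rest.
Because the slope is derived, `detection_limit()` takes it as an input and
never hard-codes it.

The detection limit is $|(\mathrm{mean} - 3\,\mathrm{SD})/\mathrm{slope}|$
of baseline %ΔF/F samples; the absolute value makes the reported magnitude
positive for either sensor polarity, and the statistic is homogeneous of
degree zero in (samples, slope) scaling.

**Spikes.** The slow indicator is treated as spike-insensitive: spikes are
recorded in the ground truth and drive the calcium channel, but add no
voltage-channel deflection. This is deliberate — the indicator family
modelled here is specialized for subthreshold signals.

# The calcium-indicator forward model

Each spike adds a unit-peak double-exponential transient
(`tau_rise` = 50 ms, `tau_decay` = 400 ms) of amplitude `a_spike` = 0.25
fractional ΔF/F; $n$ coincident spikes peak at $n \cdot a$ (linear, as the
tests verify to 1%). `subthreshold_gain` defaults to 0: a spike-free
voltage trace yields an exactly flat calcium trace, which is the premise of
the dual-channel discrimination. The closed-form kernel peak time
$\frac{\tau_d \tau_r}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)$ is the oracle for
peak-latency tests.

# Membrane-voltage dynamics

Voltage is simulated at 1 kHz. Spontaneous activity consists of
population-synchronous UP states — a renewal process with a slow-oscillation
dead time (min gap ~2.5 s, mean rate `up_rate` = 0.25 /s) so events do not
overlap — plus independent small per-cell EPSPs (0.5 /s, ~3 mV) that remain
below the detection threshold and act as physiological background. Evoked
responses begin `evoked_latency` = 40 ms after each stimulus with a fast
(10/100 ms) kernel. UP amplitude defaults to 18 mV with modest (±15%
population, ±10% per-cell) jitter: the published event analysis was
restricted to large depolarizations (> 20 mV, measured ΔF/F ≈ −3.4% at
SNR ≈ 6.6), so the generator's analyzed events are placed in that same
SNR ≈ 6 regime rather than spread into an arbitrary low-amplitude tail.
Events whose peak crosses `spike_threshold` (−52 mV) fire a 1–3 spike burst
with probability 0.9; with an 18 mV mean amplitude this yields roughly a
60/40 spiking/subthreshold mix.

# The focal-seizure scenario

A 4-AP-style focus sits `focus_offset` = 600 µm beyond the field's −x edge.
During the `preictal_window` (30 s) the focus fires interictal spikes (IIS)
whose rate ramps 0.4 → 1.2 /s. The fraction of each IIS reaching the imaged
cells as a population EPSP is zero over the first third of the window
(intact surround inhibition — the "early interictal" period in which the
LFP shows IIS but the optical channels show nothing) and then follows an
accelerating power-1.5 ramp to 1 at onset. The exponent is a compromise
the data constrain from both sides: EPSPs must already be optically
detectable 10–20 s before onset (they are counted and compared across the
0–10 s and 10–20 s look-back windows) while the LFP–optical correlation
must still increase markedly toward onset. Field EPSPs are 20 mV at full
coupling with a 20/150 ms kernel — population barrages, slower and larger
than unitary EPSPs.

At electrographic onset the focus produces a tonic depolarization
(25 mV) carrying a large ~3 Hz spike-wave-like oscillation (80% of the
plateau); the oscillation matters because the analysis band-passes the LFP
at 0.2–50 Hz, which removes a pure plateau. All imaged cells depolarize
within `ictal_sync_jitter` (50 ms SD; fast subthreshold propagation), while
spiking recruitment arrives at distance/`wavefront_speed` (100 µm/s) and
triggers an 8-spike burst, hence a large calcium transient — the slowly
travelling ictal wavefront. The LFP is synthesized as the negated, scaled
(0.1 mV/mV) population-mean depolarization of the focus, plus 0.3 mV white
instrument noise (≈0.1 mV within the 0.2–50 Hz band), digitized at 1 kHz.

# Rendering and measurement

Movies integrate the 1 kHz traces into 30 Hz frames (box average over each
frame's exposure), paint somata as disks over a neuropil background (30% of
the mean somatic signal), multiply the whole frame by the heartbeat gain
$1 + a\sin(2\pi \cdot 7\,\mathrm{Hz}\cdot t)$, apply integer rigid motion
jitter, Poisson shot noise (mean-preserving, 2000 counts per intensity
unit) and overwrite flash frames with full-scale saturation. The heartbeat
artifact belongs to one-photon wide-field imaging; the two-photon scenario
paths therefore default it to zero, and the wide-field acceptance check
renders it explicitly (7 Hz × 60 s = 420 detected peaks/min).

Because rasterizing long multi-seed experiments is slow, scenarios default
to a trace-level measurement path: frame integration plus multiplicative
Gaussian ROI noise of SD 0.55% per 30 Hz sample — the ROI-mean equivalent
of the shot noise, calibrated so a ~20 mV event has SNR ≈ 6. The rendered
and trace-level routes are exercised against each other in the tests; a
green trace-level test therefore establishes the analysis logic, while
registration, Kalman filtering and extraction are validated on shorter
rendered stacks. What the generator does **not** emulate: optical PSF and
depth sectioning, hemodynamic absorption beyond the heartbeat gain,
indicator nonlinearity in the calcium dye, dendritic signals, and non-rigid
tissue deformation.

# Preprocessing choices

*Flash frames* are replaced by their predecessor; a run of consecutive
flash frames copies the last clean frame; a flash at frame 0 (no
predecessor) copies the next clean frame. *Registration* is rigid
integer-plus-subpixel translation by FFT cross-correlation with a
parabolic peak refinement and median border fill — rotation/affine warping
is unnecessary for the simulated jitter, and the original plugin-based
registration is not reimplemented. Shift estimates are capped (default a
quarter of the image) and a binding cap raises a warning. *Kalman stack
filtering* uses the classic recursion with prediction bias 0.80 and noise
variance 0.05; the first frame passes through with predicted variance set
to the noise variance (the plugin's initialization is undocumented; this
choice is frozen here). The whole-stack implementation is required to match
an independent per-pixel scalar recursion bit for bit, which the
acceptance suite checks on 100 random stacks.

# Trace statistics

ΔF/F is stored as a fraction and reported as percent. For stimulus epochs
$F_0$ is the 0.5 s pre-stimulus mean; for spontaneous segments $F_0$ is the
slow natural-cubic-spline trend (knots every 10 s — the original analysis
names only "a spline function", so the spacing is exposed in config), which
also removes photobleaching. SNR is the response-window extremum taken in
the channel's response direction (voltage: minimum; calcium: maximum)
divided by the SD of the 0.5 s pre-stimulus baseline; the post-stimulus
search window is frozen at 1 s since no value is published.

Detection thresholds are in baseline-SD units (default 3) because only
ΔF/F, not millivolts, is observable in vivo; the mV equivalent is available
through the calibrated F–V slope. The baseline SD estimator is
$\mathrm{MAD}(\Delta y)/\sqrt{2}$ — first differences pass white
measurement noise but cancel slow physiological events, so the estimate
stays honest even when UP states occupy half the trace. The estimator
assumes white noise at the sample rate; for band-limited signals (the
0.2–50 Hz LFP) the segment MAD is used instead, and the seizure pipeline
does so explicitly. Interictal-event detection additionally requires the
excursion to last ≥ 50 ms, which suppresses single-sample noise spikes.

# Seizure analysis choices

The electrographic LFP onset is operationally defined (no published
definition exists) as the first time the 2-s moving average of the
rectified band-passed LFP exceeds 3 robust SDs — an envelope criterion, so
brief oscillation dips and isolated IIS do not trigger it, but a sustained
discharge does. Optical onsets use the same rule per trace in the channel's
response direction; calcium onsets double as recruitment times, regressed
on position to estimate the wavefront (speed = 1/|gradient|, axis = the
fitted onset-time gradient; synchronous onsets flag the speed infinite).

The optical $F_0$ trend for the seizure recording is fitted to *pre-onset*
data only and extrapolated across the seizure: a trend fitted to the whole
recording absorbs the ictal plateau and corrupts both the pre-ictal ΔF/F
baseline and the onset step. Interictal segments are additionally
detrended locally before event counting. LFP–optical correlation follows
the published two conventions: zero-lag Pearson matrices for population
structure, and full normalized cross-correlograms (after box-downsampling
the LFP to 30 Hz) for LFP-vs-OFP, reported as peak |r| and lag per
look-back window with `max_lag` = 0.5 s (the physiological lag —
propagation delay plus indicator kinetics — is 0.2–0.3 s; a wider search
only inflates the weak-window peak with noise).

# Numerical and interface choices

- Times in seconds, positions in µm, frame indices 0-based, voltage in mV.
- Stacks are multi-page 16-bit grayscale PGM (binary P5 or plain P2) with a
  JSON sidecar carrying frame rate, channel and intensity scale: a
  dependency-free standard format that round-trips losslessly up to
  quantization. No TIFF reader is available in the supported environment.
- Configs and summaries are JSON (no YAML parser in the supported
  environment); every artifact embeds a deterministic config hash.
- Seeding: one master seed; each stochastic stage draws from a child stream
  derived by hashing the master seed with a stage tag, so adding noise to
  one stage never perturbs another and every operation is a pure function
  of (inputs, seed).
- Fits use `nls` (port algorithm) with bounded parameters and log-linear or
  range-based initial guesses; port's "false convergence" on
  near-degenerate two-exponential problems is accepted because the returned
  least-squares solution is accurate (the tests cover the degenerate
  single-exponential case explicitly). The published R² formula contains an
  obvious typo (numerator and denominator swapped); the conventional
  $1 - SS_{res}/SS_{tot}$ is implemented.
- The R API is the primary interface; the CLI wraps the end-to-end paths
  (`run`, `preprocess`, `limit`) rather than re-exposing every operation.

# Known limitations

- The F–V defaults are calibrated to the derived slope and qualitative
  variant ordering only; absolute ΔF_max is not identifiable from the
  published material.
- The kinetics acceptance check at realistic noise uses a 40-sweep average
  (8 cells × 5 sweeps) as its characterization regime; single noisy sweeps
  at in vivo noise do not constrain a two-exponential fit to 15%.
- Trend extrapolation across a seizure is linear beyond the pre-onset
  boundary (natural-spline behaviour); over tens of seconds of a ~300 s
  bleach this bias is negligible, but very long ictal segments would need
  an explicit bleach model.
- The windowed-correlation escalation toward onset is a stochastic
  property: it holds in ≥ 90% of seeded runs, not universally, because the
  two look-back windows draw finite (~6–10) coupled events.
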