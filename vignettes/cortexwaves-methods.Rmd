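---
title: "Models and methods behind cortexwaves"
author: "cortexwaves authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexwaves)
```

# Scope

`cortexwaves` studies the two dominant mesoscale activity regimes of rodent
sensory cortex: **slow wave activity** (SWA) — large, stereotyped waves of
population activity that start at a focal origin, propagate across the cortex
at tens of mm/s, and are separated by silent periods — and **persistent
activity** (PA) — continuous, small-amplitude fluctuations without prolonged
quiescence. The package bundles

* a ground-truth synthetic-data generator for fiber-photometry calcium
  traces, LFP-like signals, and wide-field calcium movies;
* the analysis stack those data feed: df/f normalization, Gaussian low-pass
  filtering, threshold event detection, stimulus-locked latency estimation
  with shuffled-onset controls, cross-correlation and inter-regional delays,
  pixel-wise response-time maps, gradient-based propagation velocity fields,
  activation-probability distributions with permutation testing, multitaper
  spectrograms, band-limited log fold-change quantification, power-threshold
  slow-wave onset detection, and refractory-period estimation;
* weighted circular statistics (a permutation two-sample Kuiper test) for
  comparing propagation-direction distributions.

Because the generator knows the truth behind every rendered signal, each
analysis stage can be validated as a parameter-recovery problem; the test
suite and `scripts/acceptance.R` do exactly that.

# The generative model

## Geometry and conventions

Coordinates are stereotaxic millimetres (bregma = 0; more negative AP = more
posterior). Image rows run anterior to posterior, columns medial to lateral.
Direction angles are 0 = anterior, +&pi;/2 = lateral. The default field spans
AP +1.5 to −6.5 and ML −1.0 to +5.0 at 0.1 mm/px, with fiber/electrode sites
S1 (AP −0.2, ML 2.5) and V1 (AP −3.8, ML 2.0); the S1→V1 separation along the
AP axis is 3.6 mm, so a 30 mm/s posterior-going wave reaches V1 ~120 ms after
S1.

## Spontaneous waves

Spontaneous SWA events form a renewal process: inter-event intervals are the
hard refractory period &tau;~r~ (default 2.0 s) plus an exponential whose
mean is set so the rate matches `waveRatePerMin` (default 10/min, i.e. waves
around 0.1 Hz). Each wave receives

* an **origin**: the anterior band around the S1 AP coordinate with
  probability `anteriorOriginProb` (default 0.6), otherwise the posterior
  band around V1, with ±0.2 mm AP jitter and uniform ML jitter over 1.5–3 mm;
* a **speed** drawn from Normal(30.5, 5.3) mm/s truncated positive;
* a **direction** pointing away from its origin band along the AP axis with
  Gaussian angular jitter (SD 0.15 rad).

A wave is a plane wavefront: the activation time of any point is the event
time plus the signed projection of (point − origin) onto the propagation
direction divided by the speed. This is deliberately the simplest model
consistent with a single speed and direction per event; no wavefront
curvature is modelled.

## Stimulus gating and evoked waves

`applyStimulusGating()` walks stimuli in time order. If the time since the
most recent wave is at least &tau;~r~, an evoked wave is inserted with
probability `pEvoke` (default 0.90) at the modality's primary site (forepaw →
S1, visual → V1) after a latency drawn from Normal(mean, SD) with the
defaults 98 ± 7 ms (forepaw → S1) and 115 ± 4 ms (visual → V1); the latency
SD is the standard-error scale of the corresponding means. Distant-site
latencies are *emergent* from propagation (forepaw-evoked waves reach V1 at
roughly 98 ms + 3.6 mm / speed ≈ 215 ms). Inside the refractory window the
success probability drops to `pRefractory` (default 0.2) and a successful
response initiates only once the network recovers (last wave + &tau;~r~) plus
the usual latency — which is what makes response times far more variable for
refractory stimuli. Spontaneous events falling within &tau;~r~ after an
inserted evoked wave are absorbed by it. Evoked and spontaneous waves are
otherwise identical in amplitude and shape — nothing in the data suggests
they differ in anything but timing.

Two consequences worth noting. First, the *measured* post-refractory success
rate slightly exceeds `pEvoke`, because a failed stimulus can still be
followed by a spontaneous wave inside the 0.5-s success window (hazard
0.25/s → ≈ 0.912 instead of 0.90). Second, because the estimator's criterion
is *strictly* above 90%, a single few-hundred-stimulus experiment estimates
&tau;~r~ with appreciable noise; recovery of the refractory period is
therefore defined by the modal estimate over replicate runs (see the
refractory section below).

## Rendered signals

**Photometry** (2 kHz): the raw trace is `f0 * (1 + activity + noise)` with
`activity` the per-site sum of calcium kernels
`(1 − exp(−t/tauRise)) exp(−t/tauDecay)` (unit peak; defaults 50 ms rise,
1 s decay — a typical synthetic-dye/GCaMP scale) placed at that site's wave
onsets, and i.i.d. Gaussian noise with SD `noiseSd` (default 0.1) of the
event amplitude. PA traces instead carry band-limited fluctuations centred on
15 Hz plus a short-latency (25 ms), fast-decaying transient after every
stimulus.

**Wide-field movies** (20 Hz default): spontaneous waves sweep the full
field; evoked waves activate exactly `round(area / pitch^2)` pixels nearest
the initiating site, with the default areas 22.8/23.1 mm² (SWA visual /
somatosensory) and 6.9/7.5 mm² (PA). The near-saturating SWA footprints
mirror the observation that SWA responses engage essentially the whole
imaged window, while PA responses stay focal. Per-pixel, per-frame Gaussian
noise is added on the same relative scale.

**LFP** (2 kHz): SWA events contribute a large stereotyped delta-band onset
deflection (a damped 3-Hz transient) followed by sustained broadband
(0.5–200 Hz, with an extra band around 40 Hz) activity over the nominal 1-s
up-state; the baseline between events is ~5% of the within-event amplitude.
The prominent onset deflection is not cosmetic: a power trace thresholded at
mean + 4 SD only detects event *onsets* if the power at the onset clearly
dominates the within-event plateau, which is also how real slow-wave LFP
looks (a sharp initial deflection, then sustained elevation). PA is a
continuous narrowband process around 15 Hz over pink noise. In both states a
60-ms, 80-Hz gamma packet follows each stimulus — but only at the stimulated
modality's primary site, matching the finding that the fast primary response
does not propagate.

All renderers are bit-reproducible given `SimConfig@seed`; each generation
stage derives its own RNG stream from it.

# Analysis methods and their numerical choices

## Event detection in photometry

Traces are normalized (`normalizeDff`, raw / baseline-mean − 1; an automatic
quiet-window picker replaces manual baseline selection for reproducibility)
and low-pass filtered with a zero-phase Gaussian kernel whose −3 dB point is
20 Hz (sigma = sqrt(ln 2)/(2&pi;·20) ≈ 6.6 ms). Detection thresholds at
baseline mean + 3 SD, where the baseline statistics are median/MAD over an
iteratively refined sub-threshold mask — MAD because calcium decay tails
inside the mask would otherwise inflate the noise estimate and bias onsets
late. A crossing must persist ≥ 0.2 s; events closer than 1 s merge.

With a 1-s decay and a 2-s refractory period, consecutive waves frequently
ride on each other's tails without returning below threshold, so a plain
threshold detector would merge up to half of all event pairs. Supra-threshold
epochs are therefore split at secondary rises, detected as new upward
crossings of the derivative's own threshold; each split onset is walked back
to the start of its positive-derivative run. At the default noise level this
detector achieves recall and precision of 1.00 against generator truth, with
an onset bias of about −5 ms (SD ~10 ms) — small against the 98/115-ms
latencies it is used to recover.

## Latency maps and velocity fields

Stimulus-triggered averages use the frame before each stimulus as the df/f
reference. Pixel onsets threshold at pre-stimulus mean + 3.5 SD (1-s
pre-stimulus window). Two numerical points matter at 20 Hz:

* **Sub-frame timing.** The calcium rise spans about one frame, so the
  crossing frame alone quantizes latencies to 50 ms — useless for gradients
  at 0.1-mm pitch (the true latency step between neighbouring pixels is
  ~3 ms). `onsetLatencyMap` interpolates the crossing time with a local cubic
  spline through the pixel time course (linear fallback).
* **Gradient estimation.** Even interpolated maps retain a sawtooth residual
  with spatial period speed/frameRate (~1.5 mm), so nearest-neighbour
  differences are dominated by it, and a 3×3 median filter cannot help — a
  median filter is the identity on monotone data. `velocityField` instead
  fits a least-squares plane over a (2·10+1)-pixel window (2.1 mm, chosen to
  cover at least one sawtooth period) and takes speed = 1/|∇t| and direction
  = direction of increasing latency. Pixels implying speeds above
  1000 mm/s (near-simultaneous activation) or crossing within 25 ms of the
  stimulus (already rising at stimulus time, so no wavefront timing) are
  masked.

On a noiseless plane wave this recovers the generator speed within 1%; at
default noise, stimulus-triggered averages of ~15–25 clean evoked trials per
animal recover the 30.5 mm/s mean within a few percent when pooled over
animals. Response areas count the maximum simultaneous number of
supra-threshold pixels over the 1–2-s post-stimulus window times the pixel
area (a cumulative "ever active" mode is available; the simultaneous reading
is the default).

## Spectral analysis

Multitaper spectrograms average periodograms over DPSS (Slepian) tapers
computed from the standard symmetric tridiagonal eigenproblem — validated
against an independent reference implementation to 1e-9. The display defaults
follow the conventional parameter set (0.4-s window, 0.2-s step, TW = 4,
K = 9, fpass 0–40 Hz). Note two caveats: K = 9 exceeds 2·TW − 1 = 7, so the
two highest-order tapers are poorly concentrated (a warning is emitted, but
the convention is kept); and the estimator's resolution bandwidth is
W = TW/window = 10 Hz at these defaults, so narrowband structure spreads
accordingly — quantitative tone-localization checks use longer windows and
smaller TW.

Band-limited power uses a zero-phase FFT brick-wall band-pass, because the
canonical 0.5-Hz lower band edge at 2 kHz sampling is numerically hostile to
IIR filters and the fold-change windows are short. The fold change averages
the stimulus-locked segments first, band-limits the average, and reports
log10(post/pre mean power) with post = 0–1.5 s and pre = −0.3 to −0.1 s. The
canonical bands are sub-gamma 0.5–35 Hz, gamma 35–200 Hz, total 0.5–200 Hz.

Slow-wave onsets from LFP: power over time is the squared signal smoothed
over 100 ms; onsets are upward crossings of mean + 4 SD of that power trace
(merged below 0.5 s). The threshold is relative, hence amplitude-scale
invariant. On generator SWA signals recall is ≥ 0.95 with ≤ 1 false
positive/min.

## Refractory-period estimation

For each stimulus, the time since the last spontaneous wave is binned into
0.5-s bins from zero; a stimulus succeeds when a wave onset follows within
the success window (default 0.5 s — the natural reading of the source's
garbled "500 s"); &tau;~r~ is the lower edge of the first bin whose success
rate strictly exceeds 90% (empty bins are skipped, never passed). Because the
generator's post-refractory success sits barely above the criterion (see
above), a single 500-stimulus run yields 2.0 s only ~half the time, with 2.5
or 3.0 s otherwise; the modal estimate over replicate runs is 2.0 s
essentially always, never undershoots by more than one bin, and shifts up
when the generator's &tau;~r~ is lengthened. Latency-versus-interval tables
reproduce the companion observation: response-time SD is much larger for
stimuli inside the refractory window than outside it.

## Circular statistics

Velocity vectors pool across animals into a speed-weighted polar
distribution. Two direction distributions are compared with the Kuiper
statistic V = max(F~A~ − F~B~) + max(F~B~ − F~A~) on weighted empirical CDFs
— rotation invariant by construction and equal to the classical statistic for
equal weights (verified against an O(n²) brute-force rotation-scan oracle).
Tabulated Kuiper critical values do not apply to speed-weighted samples, so
significance comes from label permutation; with `unitsA`/`unitsB` whole
animals are swapped instead of single pixel vectors, since pixel vectors
within an animal are strongly dependent. For continuous weights the
permutation p-values are uniform under the null (Kolmogorov–Smirnov distance
< 0.05 over 1000 null simulations); for unweighted samples ties make the
add-one p-value conservative, which is the safe direction.

## Activation distributions

The field-of-view mean trace is normalized to [0, 1] with its 1st/99th
percentiles (robust against single outlier frames), histogrammed into 20
bins, and compared across states by permuting animal labels, with per-bin
two-sided add-one p-values Bonferroni-corrected over bins. SWA puts its
largest mass in the lowest activation bins (silent periods dominate); PA
occupies mid activation and is never fully silent or fully active.

# Problem sizes used in the tests and acceptance script

Simulated recordings are sized to give stable statistics while keeping the
suite quick: 300–750-s photometry/LFP recordings (50–125 waves), 4 synthetic
animals × 30 stimuli for evoked-probability recovery, 170 visual stimuli for
latency recovery, 30-stimulus wide-field sessions (~15–25 usable trials per
stimulus-triggered average) at 80 × 60 px, and 41 replicate 500-stimulus runs
for the refractory mode. Coarser 0.2–0.4-mm pitches are used where only
field-of-view means matter.

# What passing tests do and do not show

The generator reproduces the *statistical structure* the analyses target:
renewal timing with a hard refractory period, plane-wave propagation with a
single speed/direction per event, site- and modality-specific latencies,
spatially confined versus saturating footprints, gated broadband LFP power,
and state-specific spectra. It does not emulate biophysics (no network
model), hemodynamic or motion artifacts, wavefront curvature or
state-transition dynamics, awake locomotion, or inter-animal variability
beyond seed-to-seed resampling. Recovery of a parameter here therefore
demonstrates that the estimators are correct and unbiased under the stated
model, not that they are robust to everything real recordings do; the
detection thresholds, windows and smoothing scales are all exposed as
arguments so they can be re-tuned on real data.

# Known limitations

* The plane-wave model activates the half-plane behind an evoked origin
  before the primary site; analyses exclude those pixels (`clipS`) rather
  than modelling radial spread.
* Evoked-probability and leader-fraction recoveries inherit binomial noise
  from their prescribed sample sizes; tolerances are stated as binomial 95%
  confidence intervals.
* The refractory estimator's strict >90% criterion interacts with a 90%
  success probability; see the refractory section for why the modal estimate
  over replicates is the meaningful recovery target.
* `kuiperTwoSample` p-values are conservative for heavily tied (unweighted)
  samples.
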