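---
title: "Methods: firing-pattern statistics, event responses, photometry and coupling"
author: "cholinphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: firing-pattern statistics, event responses, photometry and coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholinphys)
```

cholinphys implements the analysis chain used to characterize cholinergic
neurons across the basal forebrain and ventral basal ganglia: firing-pattern
statistics from spike-train autocorrelograms, detection of event-related
firing-rate changes in a Pavlovian conditioning task, optogenetic-tagging
classification, functional cell typing, fiber-photometry dF/F preprocessing
and response quantification, cross-regional coupling measures, and the
arithmetic of anatomical tracing quantification. Every analysis is paired
with a seeded synthetic-data generator that emulates the statistical
structure the analysis assumes, so the whole pipeline is testable without
recorded data. This vignette documents the models, the tunable parameters,
and the numerical choices made where the procedures left room.

## Conventions

All timestamps are seconds stored as doubles; the public API never mixes
milliseconds and seconds (conversion happens only when formatting output
such as `refractory_ms`). All time intervals are half-open `[a, b)` so bins
tile without double counting; a value landing exactly on a bin edge (up to
double rounding, guarded by a bin-relative 1e-9 epsilon) belongs to the
upper bin. Tabular files are comma-separated with a header row, UTF-8, `.`
decimal; trial tables are tab-separated. Numbers are written with 17
significant digits so write/read round trips are lossless.

## Autocorrelograms and firing-pattern statistics

`computeACG()` counts ordered distinct spike pairs by lag into 0.5 ms bins
up to 0.5 s (one-sided: positive lags only; zero-lag self-pairs excluded;
symmetric display is a plotting concern). Counts are normalized by their
mean over all bins, so a homogeneous Poisson train is flat near 1. The mean
is taken over the full lag range up to `maxLag` (default 0.5 s, recorded in
the object) — the normalization range is a package choice since only "mean
normalization" is conventional. Very active units are capped at their first
50,000 spikes to bound memory; `nSpikesUsed` records the truncation.

Moving averages (the 2.5 ms five-point smoothing for display and index
computation, the 5 ms in vitro variant, the 10 ms trough smoothing) shrink
to the valid window at the edges rather than zero-padding: zero padding
would fabricate a trough at lag 0, exactly where the refractory estimate
looks.

Three statistics summarize each ACG:

* **Burst Index** — `(max ACG in 0–25 ms − mean ACG in 180–200 ms) /
  max(both terms)`, in [−1, 1]; +1 means all short-lag mass, negative means
  short-lag suppression; 0 when both terms are 0.
* **Theta Index** — the 5–10 Hz rhythmicity peak is located as the ACG
  maximum in the 100–200 ms lag band; the mean over ±25 ms around that peak
  is contrasted against a reference level. The reference is not part of the
  published formula, so the package uses symmetric flanking windows
  (50–75 ms and 225–250 ms) with the same max-normalization as the Burst
  Index: this keeps the index in [−1, 1] and insensitive to firing rate,
  and the choice is exposed in the configuration and recorded in output
  provenance.
* **Relative refractory period** — after a 10 ms moving average, the
  central trough is the smoothed value at the smallest lag and the
  asymptote the 180–200 ms mean; the estimate is the smallest lag at which
  the smoothed ACG recovers half the trough-to-asymptote distance. This is
  a functional quantity, not a biophysical repolarization time.

`classifyFiringPattern()` maps the three statistics onto the cholinergic
phenotypes: regular rhythmic ("Reg", refractory ≥ 40 ms and positive Theta
Index), strongly bursting ("Burst-SB", Burst Index ≥ 0.4) and Poisson-like
bursting ("Burst-PL", the remainder). The published account does not print
numeric class boundaries (they live in prior work on basal forebrain
recordings), so these defaults are configuration values, documented as
such; the test suite therefore asserts ordering and recovery properties
(bursting > Poisson > regular in Burst Index; imposed dead times recovered)
rather than absolute thresholds.

## Event-related spike responses

`computePETH()` builds per-trial spike counts in half-open bins (default
10 ms — the 500 ms analysis windows are prescribed but the bin width is
not) around each event, dropping events whose window leaves the recording.

`detectEventResponse()` runs the full detection procedure in both
directions: extremum within the 500 ms post-event window; baseline = mean
rate over the 500 ms pre-event window; response window = contiguous bins
around the extremum beyond the half-distance between extremum and baseline;
a matched window of equal length around the baseline-period local extremum
of the same sign (clipped to the baseline span — the most literal reading
of "corresponding intervals around local extremes in the baseline period");
one-sided Mann–Whitney U test on the per-trial counts of the two windows
(activation tests response > baseline, inhibition the reverse — the null is
asymmetric per direction); significance at p < 0.01 to keep false positives
low. When both directions are significant, the earlier window is the
primary response. Two numerical choices: a half-height crossing that never
returns inside the search window is cut at the window end (bounded
windows), and the extremum/crossing search runs on a Gaussian-smoothed copy
of the PETH (SD 20 ms, configurable) so single-bin count noise cannot
truncate the response window — the rank test itself always uses raw counts.
On 500 simulated null units (10 Hz, 60 trials) the empirical family
false-positive rate of the two one-sided tests is about 1–2%, and power for
a 5→25 Hz, 200 ms activation over ~100 trials is 100%.

`optotag()` declares a unit opsin-expressing when its firing during laser
pulses (10 ms after onset to offset) stays at or below 0.5 Hz and its
suppression latency is below 10 ms. The latency estimator needs two
parameters the published criterion leaves open: the baseline (mean rate
over 1 s pre-pulse) and the binning (1 ms bins, 5-point smoothed); both are
documented configuration.

`clusterCellTypes()` projects z-scored reward and punishment response
vectors onto the first three principal components and cuts a Ward-linkage
(Euclidean) hierarchical tree at four clusters; linkage and metric are
configurable since they are not printed. The cluster whose mean response is
positive after both rewards and punishments is labeled putative-cholinergic
— the defining property of that functional class; the remaining labels
(glutamatergic-like for punishment-activated, GABAergic-like otherwise) are
heuristics for orientation only.

## Fiber photometry

`preprocessDFF()` applies, in order: zero-phase (forward–backward)
Butterworth low-pass at 20 Hz on both channels; an ordinary least-squares
fit (gain + offset over the whole session) of the isosbestic 405 nm channel
to the 465 nm calcium channel; `dF/F = (f465 − f405_fitted) / f405_fitted ×
100`; and a zero-phase 0.2 Hz high-pass removing slow bleaching decay. The
Butterworth orders are not prescribed: the low-pass defaults to order 4;
the high-pass to order 2, because at a 0.2 Hz cutoff the normalized
frequency is tiny and high-order high-pass filtfilt designs are numerically
fragile — both orders are configurable and recorded in provenance. When the
405 nm channel is essentially constant the fit drops the (collinear)
intercept and estimates gain only. A robust-fit alternative is not
implemented; OLS over the whole session is the default reading of
"least-squares regression".

One consequence worth knowing: with calcium-indicator kernels of ~0.6 s
decay, the 0.2 Hz high-pass itself reshapes every transient (undershoots),
since the transient energy sits near the cutoff. Recovery tests therefore
compare the dF/F output against the ground-truth transient trace passed
through the same deterministic high-pass; this isolates what the correction
is supposed to do (remove shared motion artifact and bleaching — the
generator sessions show >99% artifact-variance reduction and >0.99
correlation) from the filter's own, faithful distortion.

`zscoreToBaseline()` aligns trials on a trigger and z-scores either per
trial (mean/SD of that trial's 2 s pre-cue baseline) or per session
(mean/SD pooled over the trials' inter-trial baselines); both modes exist
in the analysis chain and the caller chooses. Trials with zero baseline SD
are excluded with a warning.

`responseMetrics()` reports, on the trial-averaged trace: peak (maximum in
the 1 s response window), latency (its time), duration (width between the
half-maximum crossings searched outward from the peak, edge-bounded) and
AUC (sum of samples between the crossings divided by the sampling rate).
The half-maximum reference is 0 because the baseline is zero by
construction after z-scoring; crossing times are linearly interpolated
between samples.

`trialwiseCueTest()` pairs, per trial, the maximum of the 0–0.5 s response
window with the maximum of the −0.5–0 s baseline window and applies a
one-sided paired Wilcoxon signed-rank test. Reading "baseline fluctuations"
as the per-trial baseline maximum is a documented choice (mean or full
distribution are alternatives the text does not distinguish); maxima vs
maxima is the symmetric pairing and calibrates correctly on null data
(about 5% at the nominal level). Latency/duration quantification is gated
on this significance, mirrored by the `quantify` flag.

## Coupling analyses

`normalizedXCorr()` computes the cross-covariance at every lag within
±10 s, normalized by the geometric mean of the zero-lag autocorrelations,
via FFT (verified against a direct per-lag oracle to 1e-9). Signals are
mean-centered by default — the published formula operates on raw series,
but photometry offsets are arbitrary; the flag is part of the call
signature. The central ±20 ms is masked as common-mode before peak finding.
Lag sign: positive lag means the second signal lags the first; no
convention is printed, so this one is fixed and documented here.
`averageCCR()` averages sessions pointwise (union of masks) and tabulates
per-session peak value and lag.

`pupilDiameter()` is the mean Euclidean distance of the three diagonal
pupil-edge landmark pairs, with missing frames linearly interpolated and
optional resampling onto the photometry grid. `peakTriggeredAverage()`
detects z-scored calcium maxima above 2 SD with 1 s minimum separation
(greedy by amplitude) and averages a target series in a −2 to +4 s window.

`transferEntropy()` z-scores both series, optionally block-averages them to
20 Hz, discretizes each into 200 equal-width bins spanning its own range,
and evaluates the plug-in transfer entropy with a one-sample past in both
directions. History length and downsampling rate are not printed in the
source procedure and are configuration (defaults 1 sample, 20 Hz). The
plug-in estimator at 200 bins is biased upward at realistic sample counts
(the number of occupied (y_t, y_past, x_past) cells approaches the sample
count); this bias is documented, not "fixed" — the package's tests
exercise small bin counts where the estimator is well-behaved and use the
200-bin setting comparatively (between directions), which is also how the
measure is used scientifically. TE is clamped at 0 against float error and
is exactly symmetric for identical inputs.

## In vitro metrics

`detectSpikes()` finds upward −20 mV threshold crossings and assigns each
the time of the following local voltage maximum; threshold and 1 ms merge
interval are configuration (the source analysis does not state them), and
the tests use constructed traces where detection is unambiguous.
`spikeDelay()` is the interval from current-step onset to the first spike
peak inside the step (an explicit no-spike result, never 0).
`burstFrequency()` is the reciprocal mean of the three inter-spike
intervals after the first spike — algebraically `3/(t4 − t1)`; "subsequent
three ISIs" is read as the intervals between spikes 1–2, 2–3, 3–4 of the
step response. `evokedACG()` sums per-sweep pair histograms (never pairing
across sweeps), normalizes, and smooths with a 5 ms moving average; evoked
ACGs default to 1 ms bins so that window is a centered 5-point average.
Per-cell summaries report the maximum spike delay and burst frequency over
sweeps (maximum over prepolarization levels is the configurable
alternative).

## Anatomy arithmetic

`inputFractions()` expresses each region's labeled-cell count as a
percentage of the animal's total (controlling for viral spread), then
averages percentages across animals with SEM; absent regions count as 0%
and zero-total animals are excluded with a warning. `axonDensity()` reduces
a pixel-probability map to a scalar by either mean probability or the
fraction of pixels at or above a threshold (default 0.5) — the published
account does not state the reduction, so both are implemented and the mode
is recorded; `axonDensityTable()` renormalizes densities to percentages
across the sampled regions. Densities are relative: the imaged volumes are
standardized but unquantified upstream.

## The synthetic-data generators

The generators define the study conditions the tests assert under:

* Spike trains: Poisson with absolute dead time (renewal:
  `ISI = deadTime + Exp(rate)`); bursting trains (Poisson burst onsets at
  0.3 Hz, 3–6 spikes per burst at 6 ms ± 10% jitter, overlaps merged);
  regular rhythmic trains (inhomogeneous Poisson at
  `rate (1 + depth cos 2π f t)`, 7 Hz, depth 0.8, thinned by a 60 ms dead
  time).
* Task sessions: strictly increasing cue times with a 3 s consumption gap
  plus a truncated-exponential 2.5–5.5 s foreperiod; 90%/10%
  reward/omission after cue 1 and punishment/omission after cue 2; outcomes
  0.4–0.6 s after the 1 s tone ends; units are inhomogeneous Poisson with
  multiplicative gain windows after their assigned events.
* Photometry: both channels share a multiplicative bleaching decay
  (τ = 600 s), an additive random-walk motion artifact and independent
  white noise; only the 465 nm channel carries transients (double-
  exponential kernel, τ_rise 50 ms, τ_decay 600 ms — order-of-magnitude
  values for fast indicators, fixture parameters rather than scientific
  claims). Default 100 Hz sampling: the acquisition hardware samples at
  12 kHz, but every frequency the chain touches is below 20 Hz, so the
  desk-scale grid exercises the identical code paths at 1/120 of the cost.
* Coupled pairs and pupil: `y = gain · x(t − lag) + noise` on a
  smoothed-noise base trace; the pupil is a lagged, single-pole-smoothed
  copy of calcium plus noise, so TE calcium→pupil exceeds the reverse by
  construction.

Every generator seeds a local RNG stream (restoring the caller's state), is
bit-reproducible from its seed, and returns a ground-truth object with all
true parameters; a top-level seed fans out to per-component substreams so
adding a unit or generator never perturbs existing streams.

What the generators do **not** emulate: spike-sorting contamination and
drift, non-Poisson history dependence beyond dead time, wavelength-dependent
(non-shared) motion artifacts, hemodynamic contamination, indicator
saturation, pupil light reflexes, or behavioral state changes. Passing
recovery tests therefore demonstrates correctness of the computations under
the stated statistical models, not robustness to every artifact of real
recordings.

## Problem sizes in the test and acceptance runs

Simulated recordings are 400–900 s at 4–20 Hz firing, 100–112 trial
sessions, 300 s photometry at 100 Hz, 5,000–10,000-sample coupling series,
with 10–500 replicate simulations per property (500 for the null
calibration of the response detector). These sizes put every Monte-Carlo
band comfortably away from its threshold while keeping the full suite in
the single-digit minutes on one CPU.

## Known limitations

* Classification boundaries between firing phenotypes are configuration,
  not estimated; with real data they should be calibrated against
  identified populations.
* The plug-in TE at 200 bins is upward-biased at desk-scale n; use it
  comparatively or lower `te_bins`.
* The isosbestic fit assumes artifact gain is equal in both channels after
  a global affine map; wavelength-dependent artifacts are not modeled.
* The trialwise baseline statistic and the matched-baseline window of the
  response detector are documented readings of under-specified procedures;
  both are isolated behind configuration and provenance so alternatives can
  be compared.
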