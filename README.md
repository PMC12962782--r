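# cholinphys

Analysis toolkit for cholinergic-neuron physiology: spike-train
autocorrelogram (ACG) statistics and firing-pattern classification,
event-related spike-response detection in Pavlovian conditioning tasks,
optogenetic-tagging classification and functional cell typing,
fiber-photometry dF/F preprocessing and response quantification,
cross-regional coupling (normalized cross-correlation, transfer entropy,
pupil–calcium coupling), in vitro current-step metrics, and anatomical
tracing arithmetic. Seeded synthetic-data generators emulate every
statistical structure the analyses assume, so the entire pipeline is
verifiable without recorded data.

The package is aimed at systems neuroscientists working with extracellular
unit recordings, bulk calcium (fiber photometry) signals, pupillometry and
tracing data from cholinergic populations of the basal forebrain, ventral
pallidum and striatum — and at anyone who wants reference implementations
of these bespoke statistics with tested contracts.

## The statistics at the core

For a spike train, the one-sided ACG is the histogram of positive lags
between all ordered spike pairs (0.5 ms bins up to 0.5 s, mean-normalized).
Three statistics summarize it:

* **Burst Index** `BI = (max ACG(0–25 ms) − mean ACG(180–200 ms)) /
  max(both)` ∈ [−1, 1]: +1 for maximal burstiness, negative for short-lag
  suppression.
* **Theta Index**: the mean ACG in ±25 ms around the 5–10 Hz peak
  (searched in the 100–200 ms lag band) contrasted against symmetric
  flanking windows, same normalization.
* **Relative refractory period**: the lag at which the 10 ms-smoothed ACG
  recovers half the distance from its central trough to its 180–200 ms
  asymptote.

These feed a three-way classification into strongly-bursting (`Burst-SB`),
Poisson-like bursting (`Burst-PL`) and regular rhythmic (`Reg`) phenotypes.

Event responses are detected on peri-event time histograms: the extremum
within 500 ms post-event, half-height response window, a matched window
around the baseline-period extremum, and a one-sided Mann–Whitney U test on
per-trial counts at p < 0.01; when activation and inhibition are both
significant, the earlier one is the primary response.

Photometry preprocessing follows the isosbestic-control chain: 20 Hz
zero-phase Butterworth low-pass, least-squares fit of the 405 nm channel to
the 465 nm channel, `dF/F = (f465 − f405_fit)/f405_fit × 100`, 0.2 Hz
high-pass, and per-trial (or session-ITI) baseline z-scoring. Coupling
between regions is quantified by cross-correlation normalized to the
zero-lag autocorrelations (±10 s window, ±20 ms common-mode exclusion) and
by plug-in transfer entropy on z-scored, downsampled series discretized
into 200 equal-width bins.

See `vignettes/cholinphys-methods.Rmd` for the full model descriptions,
parameter defaults and numerical choices.

## Worked example

```r
library(cholinphys)

# three synthetic units with known phenotypes
trains <- list(
  genBurstingTrain(duration = 600, seed = 1, unitId = "unit_a")$train,
  genPoissonTrain(15, 400, seed = 2, unitId = "unit_b")$train,
  genRegularThetaTrain(duration = 900, seed = 3, unitId = "unit_c")$train)
firingPatternTable(trains)
#>   unit_id n_spikes_used burst_index theta_index refractory_ms    label
#> 1  unit_a           750      0.9978    -0.28626           0.0 Burst-SB
#> 2  unit_b          6048      0.0947     0.00824          15.8 Burst-PL
#> 3  unit_c          2840     -1.0000     0.42271          60.2      Reg
```

The bursting unit concentrates its ACG mass below 25 ms (`BI ≈ 1`); the
Poisson unit is flat (`BI ≈ 0.09` — the max over a noisy flat band sits
slightly above the long-lag mean); the regular rhythmic unit's 60 ms dead
time empties the short-lag band (`BI = −1`, refractory ≈ 60 ms) and its
7 Hz modulation produces a positive Theta Index.

```r
# a reward-activated unit in a simulated conditioning session
sess <- genTaskSession(nTrials = 112, responseSpec = list(
  unit_a = list(base_rate = 5, event = "reward", latency = 0.02,
                duration = 0.2, gain = 4)), seed = 7)
peth <- computePETH(sess$trains$unit_a, sess$events$reward,
                    c(-0.5, 0.5), 0.01)
r <- detectEventResponse(peth)
#> primary: activation  window: [20, 220] ms  p = 2.51e-16

# photometry: correct, z-score to baseline, quantify
g  <- genPhotometry(duration = 300, fs = 100, seed = 21)
cs <- preprocessDFF(g$session)
cs
#> CalciumSignal: 30000 samples @ 100 Hz; dF/F range [-1.545, 3.149] %
tp <- zscoreToBaseline(cs, g$truth$transient_times[3:20], window = c(-2, 4))
responseMetrics(tp)
#> peak 10.79 z, latency 130 ms, FWHM 469 ms, AUC 3.95 z*s
```

The detected activation window brackets the simulated 20–220 ms gain
window, and the transient-aligned dF/F average peaks at the latency and
width implied by the generator's indicator kernel.

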