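---
title: "Methods: acceleration summary measures and 24-hour activity profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acceleration summary measures and 24-hour activity profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Research-grade wrist accelerometers record tri-axial acceleration in
gravitational units (g) at 10-100 Hz. Turning those streams into a 24-hour
profile of sleep and physical-activity (PA) intensity requires (a) a scalar
*acceleration summary measure* per epoch, (b) segmentation of non-wear and
sleep, and (c) a mapping from per-minute summary values to the five standard
categories: sleep, sedentary, light, moderate, and vigorous PA (boundaries
conventionally tied to 1.5, 3, and 6 metabolic equivalents). `wristpa`
implements this pipeline end-to-end with interpretable, threshold-based
classification, plus the machinery to learn thresholds from labeled data and
to fuse several measures with a random forest.

## The four summary measures

All measures operate on axes $x_t, y_t, z_t$ in g and are summarized on
1-minute epochs labeled by their start minute (half-open interval).

* **ENMONZ** - Euclidean norm minus one, clamped:
  $\max(\sqrt{x_t^2+y_t^2+z_t^2}-1,\,0)$ per sample. Removes the static 1 g
  of gravity; the clamp suppresses negative residuals from calibration error
  or orientations where the dynamic component opposes gravity.
* **MAD** - mean amplitude deviation: within a window of $N$ samples, the
  mean absolute deviation of the Euclidean norm from its window mean.
* **AI** - Activity Index: per 1-second window, the mean of the three
  per-axis *population* (1/N) variances, minus an optional device noise
  variance (default 0), clamped at zero; the sixty 1-second values of each
  minute are **summed**, not averaged.
* **ROCAM** - rate-of-change acceleration movement: the Euclidean norm of
  successive per-axis differences,
  $\sqrt{\Delta x_t^2 + \Delta y_t^2 + \Delta z_t^2}$, passed through a
  running median whose length is the number of samples in one second.
  Differencing removes gravity without calibration; the median filter
  suppresses isolated spikes.

Numerical choices where the definitions leave room:

* *MAD window*: the window length $N$ is not fixed by the definition; the
  default is the full 1-minute epoch, so the epoch "average" is the single
  window value. Shorter windows (e.g. the 6-s convention of earlier
  activity-counting work) are available via `measure_config()`.
* *AI form*: the package follows the printed 1/N variance form; the original
  Activity Index's noise-variance subtraction is available through
  `ai_noise_variance` but defaults to 0.
* *ROCAM first sample*: the $t=0$ difference is undefined; it is set equal
  to the $t=1$ value before filtering, preserving output length with
  negligible effect at minute scale.
* *ROCAM units*: differences are per sample, not per unit time, because the
  default cut-points are stated for 10 Hz data; cut-points are therefore
  sample-rate specific by construction (see below).
* *Median filter*: even window lengths use the lower median; edges use
  shrinking windows.
* *Epoch alignment*: epochs are clock-aligned to the minute grid; partial
  leading/trailing minutes are dropped, and epochs with incomplete raw
  coverage are flagged `unknown` and excluded from all accuracy statistics.

Every measure is rotation invariant (norms, covariance traces, and
difference norms), non-negative, and matches a naive loop evaluation to
1e-10 relative error; the test suite asserts all three properties.

## Down-sampling

`downsample()` reduces 100 Hz streams to 50/25/10 Hz (any rational ratio)
with a linear-phase FIR anti-aliasing filter. The published description of
this step names only a standard FIR filter with anti-aliasing, so the design
here is a conservative standard choice, recorded explicitly:

* Kaiser-window design, stopband attenuation >= 60 dB;
* passband edge at 0.45 x target rate, stopband edge at 0.55 x target rate;
* each polyphase branch normalized to unit DC gain, so constants pass
  through exactly (the DC error is below 1e-6 g by construction);
* zero-phase compensation by removing the integer group delay of the
  odd-length symmetric filter, with reflect padding at the ends;
* every target rate is produced independently from the original record,
  never by cascading.

The first and last 60 s of a resampled record are flagged as an edge region
and excluded from epoch statistics by default — a deliberately generous
margin relative to the actual filter transient. Up-sampling is refused:
information above the source Nyquist frequency cannot be recovered.

Because per-sample differences grow as the sampling interval grows, ROCAM
values rise as the rate falls for the same motion; the per-epoch ROCAM of a
fixed band-limited signal is monotone increasing through 100/50/25/10 Hz.
This is why threshold sets carry a `sample_rate_hz` tag and
`classify_epochs()` warns loudly on a rate mismatch.

## Non-wear and sleep

**Non-wear**: a minute is *stationary* when all three per-axis standard
deviations within it are at or below 13 mg (`stationarity_sd_g`, a widely
used stationarity convention; the qualitative rule is "prolonged
stationarity"). Maximal stationary runs of at least 60 minutes are flagged
non-wear. Detection depends only on deviations, so it is invariant to
constant axis offsets.

**Sleep** is detected in two stages on the worn minutes: (1) *candidates* -
minutes whose ROCAM epoch value is below `candidate_threshold` **and** for
which at least `quiet_fraction` of the minute's 1-second mean-ROCAM
sub-windows are below the same threshold; (2) *joining* - candidate
segments separated by at most `join_gap_minutes` are merged, and merged
blocks of at least `min_block_minutes` are accepted. Defaults:
`candidate_threshold = 0.06` g (the sedentary floor of the default ROCAM
cut-points - sleep lives below the lowest sedentary threshold),
`quiet_fraction = 0.9`, `join_gap_minutes = 30`, `min_block_minutes = 30`.
The quiet-fraction criterion is this package's realization of a
short-segment sleep statistic whose exact published form is not available;
it is parameterized so an alternative statistic can be substituted. Sleep
onset/offset are reported as the first/last minute of each accepted block.
An ambient-light criterion is deliberately absent (the light modality is
not part of the supported input). Non-wear minutes are never sleep.

## Threshold classification

A `threshold_set` holds four ordered cut-points: sleep floor,
sedentary/light, light/moderate, moderate/vigorous. Bands are half-open
with inclusive upper bounds (`lower < x <= upper`); a value exactly at a
cut belongs to the lower band, and anything above the last cut is vigorous.
Per-minute precedence is total: non-wear mask, then sleep mask, then value
bands (values at or below the sleep floor are sleep). The shipped 10 Hz
defaults live in `inst/extdata/thresholds_10hz.csv`; the published ENMONZ
sedentary band starts at zero, which is represented here as a 1e-4 g floor
because the container requires a strictly positive sleep floor.

## Learning thresholds

`optimize_thresholds()` maximizes pooled minute-wise accuracy over the four
awake PA levels (sleep and non-wear minutes never enter the objective):

* **Initialization**: per-class densities are estimated with a Gaussian KDE
  whose bandwidth comes from the diffusion fixed-point rule (solved in the
  DCT domain); each adjacent-class cut starts at the minimizer of the summed
  densities between the two class modes, taking the midpoint of the flat
  plateau when the classes are widely separated. Missing or degenerate
  pairs fall back to the midpoint of that cut's bounds with a warning.
* **Search**: the accuracy objective is piecewise constant in each cut, so
  gradient methods stall. The package uses a bounded, derivative-free
  coordinate search: candidates drawn from observed-value quantiles inside
  each cut's feasible window (bounds intersected with neighboring cuts),
  followed by a data-midpoint polish around the incumbent. Ties break
  toward the smaller cut, making the search deterministic. The returned
  accuracy is never below the initialization's.
* **Bounds**: by default each cut is bounded by the 5th percentile of its
  lower class and the 95th percentile of its upper class - a reproducible
  proxy for visual inspection of the stratified distributions that also
  prevents dominant classes from absorbing their neighbors.
* Convergence tolerance 1e-6 on the objective; evaluation cap 5000.

Whether the training objective should be pooled over minutes or averaged
per participant is not fixed by the published description; pooled is
implemented because it matches minute-wise accuracy reporting.
Generalization is assessed with `lopo_run()` /
`lopo_run_multi()`: leave-one-participant-out folds, per-fold confusion
matrices, and both the pooled-matrix accuracy and the unweighted mean of
per-participant accuracies (they differ when participants contribute
unequal minutes, so both are always reported).

## Random-forest fusion

`fit_combiner()` trains a 500-tree random forest on the per-minute
estimates of the four measures (one-of-k encoded: 5 categories x 4 measures
= 20 columns; `mtry = floor(sqrt(d))`). Modes using the raw measure values
instead of, or alongside, the estimates are implemented; estimates-only is
the default as the computationally simplest variant with similar combined
behavior. The forest only re-labels awake, worn minutes - mask precedence
is applied after prediction. In the LOPO harness the forest is trained
within each fold, keeping all reported numbers out-of-sample. No class
rebalancing is applied by default (threshold precedence already limits
class dominance); `class_weights` exists for skewed cohorts.

## The synthetic-data generator

`generate_day()` emulates a minute-labeled free-living day. Per scheduled
category segment the signal at 100 Hz is

$$ a_t = \hat g_t\,(1 + r_t) + o_t + \varepsilon_t $$

where $\hat g_t$ is a unit gravity direction performing a slow random walk
on the sphere (per-category rate, interpolated per sample and renormalized,
so the gravity component has unit magnitude before noise), $r_t$ is a
radial sinusoid at half the category amplitude, $o_t$ are per-axis
sinusoids at the other half, and $\varepsilon_t$ is white noise. Two
deliberate design choices:

* *Radial/tangential split*: EN-based measures (ENMONZ, MAD) respond, to
  first order, only to the component of motion along gravity. A purely
  per-axis oscillation with random phases makes that projection a lottery
  over phase draws, so category responses would not be monotone. Fixing
  half the amplitude along gravity makes all four measures respond
  deterministically and monotonically to the amplitude ordering
  sleep < sedentary < light < moderate < vigorous.
* *Frequency detuning*: the per-axis and radial frequencies are detuned by
  a few percent so relative phases sweep within each minute; minute means
  then do not depend on the random phase draw, which keeps the calibration
  below stable across seeds.

Category frequencies are 0.5-2.5 Hz (ordinary arm-movement range, safely
inside the 10 Hz passband) and the default amplitudes (0.120, 0.281,
0.476, 0.557, 0.703 g) were calibrated once, by fixed-point iteration on
generated days, so that the per-category mean ROCAM of 10 Hz data lands at
the midpoint of the corresponding default band (e.g. light in
(0.175, 0.400] g). Days are generated at 100 Hz and passed through
`downsample()` to the requested rate, exactly as a real 100 Hz recording
would be. Per-minute amplitudes carry ~2% lognormal modulation;
`generate_cohort()` adds ~1.5% per-participant amplitude jitter - mild
enough that categories stay inside their bands (the moderate band,
(0.400, 0.483] g, is only +/-9% wide around its midpoint, which is what
caps how much between-person variation the default calibration can absorb).
Schedule boundaries fall on minute edges; the first minute of each new
segment is flagged so recovery tests can exclude transition effects
(filter smearing, sleep-block joining).

What the generator does *not* emulate: physiological gait or sleep
micro-structure, postural transitions inside a minute, device calibration
error, temperature drift, or the label noise of camera/diary annotation.
Passing tests therefore demonstrate the pipeline's correctness and
self-consistency, not field accuracy on real recordings; real-data
accuracy must be established against labeled recordings.

## Problem sizes and runtime choices

The test suite and the acceptance script run on synthetic cohorts sized for
a desktop: 3-4 participants of 24 h at 10 Hz for end-to-end checks
(generated at 100 Hz, ~8.6 M samples per day before down-sampling), shorter
6-hour schedules for the LOPO/fusion properties, 20,000 Gaussian epochs for
optimizer recovery, and 10,000 samples for the measure oracles. These sizes
were chosen so the whole suite completes in a few minutes while every
statistic remains stable to well under its test tolerance.

## Known limitations

* Published cut-points are shipped only for 10 Hz data; other rates must be
  regenerated with `optimize_thresholds()` on labeled epochs at that rate.
* The sleep detector's candidate statistic is a parameterized stand-in (see
  above); its defaults were chosen for the synthetic conditions and should
  be re-tuned on polysomnography- or diary-labeled data before clinical use.
* The optimizer finds the best cut on a quantile-candidate grid refined by
  data midpoints; with heavily tied data the deterministic tie-break toward
  smaller cuts can sit at the lower edge of an optimal plateau, which is
  intentional but means learned cuts should be read as band edges, not
  centers.
* Binary device formats (.cwa and similar) are out of scope; convert to
  `time,x,y,z` CSV first.
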