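---
title: "cardiobeat: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiobeat: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiobeat)
```

# Scope

`cardiobeat` analyses functional recordings of spontaneously beating
cardiomyocyte preparations: force-versus-time mechanocardiograms (MCG)
from an AFM cantilever resting on a contracting embryoid body,
multichannel extracellular field potentials from a multielectrode array
(MEA), and calcium line-scan fluorescence.  From these it derives the
field's standard readouts — beat rate (BR), contraction force (R-S span),
R-R interval statistics, cutoff-defined arrhythmic events with
contingency testing, calcium transient kinetics and diastolic spark
rates — and runs the group-comparison layer used in in vitro
cardiotoxicity screens.

Because raw instrument recordings are large and external, the package
ships a phenomenological signal simulator with complete ground truth.
The simulator is a first-class, tested module: every detector in the
package is validated against schedules, amplitudes and event lists it
knows to be true.

# The beat schedule model

`generateBeatSchedule()` draws inter-beat intervals around the base
period $60/\mathrm{BR}_0$ with Gaussian jitter of coefficient of
variation `rateJitterCV` (truncated at 10% of the mean to keep intervals
positive).  Two arrhythmia phenotypes can be overlaid:

* **Stochastic extreme pauses.**  A Poisson-distributed number of
  intervals (mean `pauseRate` per 1000 beats) is *replaced* by a pause
  drawn uniformly from `pauseDurationRange`.  Replacing rather than
  adding keeps the mapping between injected pauses and extreme R-R
  intervals exactly one-to-one: the ground truth records the interval
  index, and the scored extreme interval equals the drawn pause.  The
  pause range must exceed the arrhythmia cutoff it is meant to trigger;
  the constructor of `experimentConfig()` enforces this.
* **Tachy–brady alternation.**  A square wave of period
  `tachyBradyPeriod` multiplies the rate by `tachyBradyRateRatio` in one
  half-period and divides it in the other — the simplest model of
  alternating fast and slow beating episodes.  In the jitter-free limit
  the intervals take exactly two values, which the tests assert.

All generators take an explicit `seed` and restore the caller's RNG
state, so identical parameters and seed give bit-identical output.

# Waveform models

**MCG.**  The contraction template is an asymmetric biphasic pulse:
half-cosine upstroke over the quarter event width before the R peak,
fall to an S trough at `relaxationDepthFraction` times the amplitude
below baseline, and recovery to baseline within the event width.  The
morphology of real force traces is instrument- and preparation-specific;
this shape is the minimal one that makes "R peak" and "S trough"
well-defined smooth extrema, so the configured R-S span is
`amplitude * (1 + relaxationDepthFraction)` exactly.  Default sampling
1 kHz, noise and sinusoidal drift optional.

**MEA.**  Each beat produces a biphasic derivative-of-Gaussian spike on
every good channel with a fixed channel latency below 10 ms; bad
channels carry noise only (at twice the nominal SD).  Default sampling
10 kHz.

**Calcium.**  Transients rise linearly over `riseTime` and decay
exponentially with time constant $\tau$; sparks are Gaussian bumps of
FWHM `sparkWidth` and amplitude `sparkAmplitudeFraction` times the
transient amplitude, placed uniformly at random in diastolic intervals.
Default line rate 100 Hz.  Two generator details matter for
interpretation: sparks are kept at least one spark width away from
transient spans, and a minimum inter-spark spacing of two spark widths
is enforced — at 100 Hz two releases 30 ms apart fuse into a single
bump and are experimentally indistinguishable from one event, so
counting them separately in the ground truth would make any detector's
"recall" undefined rather than informative.

# The R/S detector

`detectBeats()` is one detector core shared by MCG and MEA analysis
(presets differ only in refractory period: 250 ms for slow human
PSC-derived clusters, 100 ms for the fast murine HL-1 line).  The
pipeline is: optional moving-median detrending, optional short
moving-average smoothing, candidate local maxima, an adaptive
*topographic prominence* threshold, refractory pruning, and S-trough
assignment (the earliest minimum between each R and the next R).

Numerical choices worth recording:

* **Adaptive threshold.**  Prominence must exceed
  `prominenceFraction` (default 0.3) of the robust amplitude range,
  defined as the 99.95th percentile minus the median of the processed
  signal.  A MAD-based scale was considered and rejected: MEA spikes
  occupy well under 0.5% of samples, so any MAD-like (or even 99.5th
  percentile) statistic sits inside the noise floor and the threshold
  collapses.  The 99.95th percentile still lies on the event peaks for
  every signal this package simulates or targets, yet is robust to a
  handful of gross outlier samples.
* **Guard band.**  Prominence is computed ignoring samples within half
  a refractory period of the candidate: noise can place a marginally
  higher sample on the same summit, which would otherwise zero the
  candidate's prominence and drop a real beat.
* **Edges.**  Smoothing uses reflection padding and the detrending
  baseline is constant-extended across the edge zones, so a beat at the
  very first sample survives; boundary samples are admitted as
  candidate peaks.  Ties resolve to the earliest sample, making the
  detector fully deterministic.
* **Deflection estimates.**  With smoothing off (clean recordings) the
  deflection is the extremal sample — exact in the noiseless limit.
  With smoothing on, the extremal sample is biased upward by noise
  selection (it is a max over noisy samples), so the deflection is the
  local mean around the extremum instead; this keeps the mean R-S
  estimate unbiased to well under 1% at 2–3% noise.
* **Detrending window** is three times the median beat period,
  estimated by a first detection pass without detrending; it falls back
  to 2 s when that pass finds too few events.

Flat or non-finite traces return an *empty* `BeatSeries` with a warning
rather than an error, so one dead recording does not abort a batch.

BR is defined as $60/\overline{RR}$ (insensitive to partial beats at
segment edges); the count-based alternative `nEvents/duration` is also
available from `beatMetrics()`.

# MEA channel quality control

A channel is rejected when its spike SNR (median detected spike
amplitude over the MAD-based noise SD of the raw channel) falls below 5,
or when its beat count deviates from the across-channel median by more
than 25% — the operational meaning of "noisy" and "non-representative"
here, since no published criterion exists.  Fewer than three accepted
channels rejects the recording outright.  The recording-level BR is the
mean of per-channel BRs; the R-R sequence used for arrhythmia scoring
comes from the single highest-SNR accepted channel, avoiding artifacts
from merging interval sequences across channels with different
latencies.  Amplitudes never propagate to MEA summaries: extracellular
spike amplitudes do not measure contraction force, and a contract test
enforces their absence.

# Arrhythmia scoring

An R-R interval is an arrhythmic event when it *strictly* exceeds the
cutoff — 3 s for hPSC-CM-type recordings, 1 s for HL-1-type (the faster
murine line).  Counts are pooled across recordings within an arm into a
2×2 table against control (the per-recording breakdown is retained),
rates are reported per 1000 intervals, and the table is tested with the
Yates-corrected chi-square

$$X^2 = \frac{N\,(\max(|ad-bc| - N/2,\ 0))^2}{(a+b)(c+d)(a+c)(b+d)},
\qquad \mathrm{df}=1,$$

with the continuity correction clamped at zero so near-homogeneous
tables cannot yield a spurious positive statistic.  The test suite
verifies this closed form against an independent cell-wise
$\sum(\lvert O-E\rvert - \tfrac12)^2/E$ computation and against
`stats::chisq.test(correct = TRUE)`.  Poincaré (lag-1 return map) pairs
with cutoff flagging are provided for the standard rhythm-irregularity
visualization.

# Calcium kinetics

Fluorescence is normalized as $\Delta F/F_0$ with $F_0$ the 10th
percentile of the raw trace (a diastolic-baseline estimate).  Transients
are peaks above 50% of the robust maximum amplitude (with an absolute
floor of 0.2 $\Delta F/F_0$ to ignore noise-only traces); the onset is
the last upward crossing of 10% of the peak before it, and the decay
time is the sample-interpolated time from peak to 10% of peak.  That
definition makes the decay time testable analytically: a pure
exponential of constant $\tau$ gives decay time $\tau\ln 10$, which the
tests assert across a 20-fold $\tau$ range.  A half-decay definition is
available via `decayTo = 0.5`.

Sparks are detected only in diastole (outside transient spans, onset to
peak plus 1.3 decay times ≈ 3$\tau$ past the peak, matching the
simulator's transient-exclusion span).  The diastolic trace is smoothed
with a 3-point moving average, a running-median local baseline
(window 0.35 s) is subtracted — without this, noise riding the decaying
transient shoulder produces false sparks just after each transient —
and local maxima exceeding $k = 3.8$ diastolic noise SDs (MAD-based)
but staying below the transient threshold are sparks.  All thresholds
are relative to the trace's own noise and amplitude, so the spark rate
is invariant to rescaling the fluorescence, and the false-spark rate on
spark-free noisy traces stays below 0.1 events/s.

# Group statistics

The comparison layer mirrors common practice for such screens: ROUT-style
outlier screening at $Q = 1\%$, heteroscedasticity-robust ANOVA with
post hoc pairwise comparisons, classical ANOVA and Kruskal–Wallis as
alternatives, and dose-trend regression.

* **Outlier screening.**  ROUT is defined for robust regression; applied
  to a single group of scalar metrics it degenerates to a robust
  location/scale screen: residuals from the median scaled by the MAD,
  two-sided $t$ tails ($\mathrm{df}=n-1$), Benjamini–Hochberg at rate
  $Q$.  This is a deliberate, documented simplification.
* **Welch ANOVA** uses the standard weighted statistic with Satterthwaite
  denominator df (verified to machine precision against
  `stats::oneway.test`).  **Brown–Forsythe** uses the means-test variant
  $F^* = \sum n_j(\bar x_j - \bar x)^2 \big/ \sum(1 - n_j/N)s_j^2$ with
  Satterthwaite df; with equal group sizes it coincides exactly with the
  classical F, which the tests exploit as an identity check.  Note the
  often-quoted claim that Welch's F "reduces to the classical F when all
  variances and sizes are equal" is exactly true only for two groups
  (where Welch $F = t^2$); for $k>2$ the denominator correction keeps
  them apart, so the two-group identity is what the suite asserts.
* **Games–Howell** refers Welch-type pairwise $t$ statistics to the
  studentized range via $q = |t|\sqrt2$; for two groups this reproduces
  the Welch $t$-test p-value exactly.
* **Dose-trend regression** is OLS of the relative response on
  $\log_{10}$(concentration) — ladders here span up to three decades, so
  a linear concentration scale would let the top dose dominate the fit;
  the linear scale remains available.  Normality tests gate nothing:
  parametric and rank-based results are always computed side by side.

# The virtual experiment

`runVirtualExperiment()` chains the whole pipeline per the standard
design: for each preparation, a baseline segment and a treated segment
are simulated from the same preparation-specific rate and amplitude
(lognormal between-preparation CVs, defaults 10% and 15%), the drug
multiplies rate by $1 + s\,(\log_{10}c - \log_{10}c_{\min})$ with
chronotropy slope $s$ per decade, force by a per-concentration inotropy
profile, and every treated recording receives the concentration-
*independent* pause rate — the stochastic arrhythmia phenotype.  The
per-recording relative response (treatment/baseline) is screened for
outliers and fed to the ANOVA layer, the contingency tests and the dose
regressions; calcium line scans are simulated and analysed for the
control arm and the top concentration.  A manifest (config + seed +
package version) reproduces a run byte for byte.

Defaults are stated once and not tuned: chronotropy slope 0.1/decade;
inotropy profile (1.25, 1.30, 1.25, 1.20) — a non-monotone hump
mirroring a significant force increase at the lowest dose with no linear
concentration relation; treated pause rate 20/1000 beats vs 2/1000 in
controls; base rates 40 bpm (hPSC-CM-like, cutoff 3 s) and 120 bpm
(HL-1-like, cutoff 1 s); response CVs 5% (BR) and 20% (force), the
scatter scale visible in published relative-response plots.  Measurement
windows default to a desk-scale 60 s rather than the wet-lab protocol's
5–10 min; every reported metric is a rate or a normalized ratio, so the
window length affects only variance.

# What a green test does and does not establish

The simulator emulates beat-to-beat jitter, drift, additive Gaussian
noise, unusable channels, drug effects and two arrhythmia phenotypes.
It does not model waveform-shape changes under drug, non-Gaussian
artifact bursts, electrode drift-outs mid-recording, cell movement in
the confocal line, ratiometric dye behaviour, or any ionic/biophysical
mechanism (no cAMP or ryanodine-receptor kinetics — the simulator is
phenomenological by design).  Green recovery tests therefore establish
that the detectors are correct and calibrated *for signals of this
class*, not that they are robust to every failure mode of the
instruments.

# Known limitations

* The spark detector reports temporal width only; 2-D spark morphology
  (spatial FWHM) is out of scope, and a kymograph input is reduced by
  spatial averaging.
* BR from mean R-R is biased downward when extreme pauses are frequent;
  this is inherent to the definition, concentration-independent by
  construction, and the count-based rate is reported alongside.
* Games–Howell p-values rely on `ptukey`, whose accuracy degrades for
  very small fractional df (tiny groups with wildly unequal variances).
* The field-potential analysis extracts timing only; no
  field-potential-duration (QT-like) analytics are attempted.
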