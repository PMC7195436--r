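---
title: "Critical slowing down biomarkers and phase-based seizure forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical slowing down biomarkers and phase-based seizure forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(czdown)
```

# The scientific problem

A dynamical system approaching a saddle-node (fold) bifurcation relaxes ever
more slowly back to its equilibrium after perturbations. In recorded signals
this *critical slowing down* appears as growing autocorrelation and growing
variance. If seizure onset is a fold transition of cortical dynamics, those
two statistics -- extracted from chronic intracranial EEG (iEEG) -- become
seizure-susceptibility biomarkers, and their slow circadian and multidien
(multi-day) modulation becomes a forecasting signal.

`czdown` implements that analysis chain for long-duration iEEG stored as
periodic short snapshots (natively: 16 channels at 400 Hz, 1-s snapshots
every 2 min over months), together with a fully labelled synthetic-recording
generator so every stage is testable without clinical data.

# The bistable state model

The generator and the conceptual analysis rest on a one-dimensional cubic
state equation

$$\frac{dz}{dt} = -z^3 + 10^{-3} r\, z + 10^{-3} k,$$

where `z` is an abstract cortical state (e.g. a mean membrane potential) and
`k` a slow physiological drive. For `r > 0` the system is bistable between
two folds at $z^* = \pm\sqrt{10^{-3}r/3}$, $k^* = 10^3 z^{*3} - r z^*$
(`critical_point()`); with the reference shape `r = 500` the folds sit at
$k \approx \mp 136$. Linearizing at a stable equilibrium gives the
relaxation time constant $\tau = 1/|{-3z_{eq}^2 + 10^{-3} r}|$
(`linearized_time_constant()`), which diverges at the fold -- the defining
signature the biomarkers track.

Time units: 1 model time-unit = 1 hour, so a circadian drive spans 24 units.
`simulate_state()` integrates the equation by Euler--Maruyama (`dt = 0.01` h;
halving `dt` moves deterministic fold-crossing times by less than one 2-min
reporting sample, which is verified in the tests). When the state crosses
the unstable branch upward a seizure is recorded, the trajectory is held
ictal for a lognormal duration (median 60 s), then reset to the lower branch
with a refractory hold (default 10 min) during which re-entry is suppressed
-- without that clamp the state can silently stick on the ictal branch
whenever the drive exceeds the fold.

# The synthetic recording

`synthesize_segments()` renders the latent state into iEEG-like snapshots:
each 1-s, 400-Hz segment is a stationary AR(1) snippet whose correlation
time is `tau_samples_per_unit` (default 3) samples per unit of the local
linearized $\tau$, plus independent white measurement noise per channel.
Innovation variance is fixed, so the stationary variance and the
autocorrelation width both grow as the drive approaches the fold -- the
minimal generator that provably exhibits critical slowing down, chosen
because the linear response of the model is proportional to its
autocorrelation function. Ictal intervals are rendered as large-amplitude
(10 x baseline SD) 6-Hz oscillations; only their detectability matters.

Epileptiform spikes are template-shaped transients (default: 0.2-s biphasic
sharp wave) injected at Poisson times whose hourly rate is modulated by the
slow drive; each channel receives an independent lognormal rate factor, so
spikes are spatially heterogeneous while the slowing signature is shared
across channels. `spike_snr` scales the template so its RMS is a multiple
(default 5) of the segment background SD; at that level the 0.85
template-correlation detector recovers over 95% of planted events.
The default base rate (600/h, i.e. 10/min) is at the active end of
clinically reported interictal discharge rates; at the original 2-min/1-s
duty cycle a much sparser process would leave the per-segment counts almost
all zero and the spike-rate rhythm undefined.

Dropouts are either explicit gaps or a random-gap model (lognormal lengths,
"minutes to days") that fills to a target missing fraction; the study-wide
average of 26% missing data is reproduced within +/-3 points per seed.

Defaults for the drive (`k_baseline = 40`, circadian amplitude 65,
multidien amplitude 55, period 10.5 days, `noise_sd = 0.1`) place the
combined peak slightly above the fold, so transitions are near-deterministic
at the strongest peaks and noise-triggered nearby: seizure rates land at
0.3--0.8/day and seizure phase-locking (SI) at 0.75--0.9, matching the range
reported for real patients. The paper states neither the noise amplitude
nor the drive waveform of its illustrations; these are this package's
choices, fixed here.

What the generator does *not* emulate: biophysical neural-mass dynamics,
multifocal spread, within-seizure secondary transitions, electrode drift,
artifacts other than the modelled dropouts, and non-stationary cycle
periods. A green test therefore establishes that the pipeline recovers
what the model world contains -- not that any clinical recording behaves
this way.

# Biomarker extraction

Raw 3-s snapshots are low-pass filtered at 170 Hz (to remove a ~200-Hz
device-charging artifact) and the first and last seconds discarded. No FIR
design tool is available in the supported environment, so the filter is an
in-package Hamming-windowed sinc (101 taps, linear phase, delay
compensated); its measured response is checked against the analytic
response in the tests (190 Hz attenuated below 5%, 10 Hz within 2%).

Per segment and channel three biomarkers are computed:

* **variance** with the population (divisor *T*) normalization;
* **ACFW**, the width at half maximum of the biased autocorrelation
  function $C_\lambda = \frac{1}{T}\sum_{t=1}^{T-\lambda}(y_t-\bar y)
  (y_{t+\lambda}-\bar y)/V_y$ -- the sum truncates at $T-\lambda$ but the
  prefactor stays $1/T$, implemented literally; the half-maximum crossing
  uses linear interpolation at the *first* downward 0.5-crossing, and an
  ACF that never reaches 0.5 within `max_lag` (default 200, half the
  1-s window; the study states no lag range) returns `max_lag` with a
  saturation flag;
* **spike rate**, detections per segment from signed sliding Pearson
  correlation against the template (threshold 0.85) with non-overlap
  suppression of one template length. Polarity is part of the template
  semantics, so flipped transients do not match.

Masked segments yield missing values in every biomarker, never numbers.
ACFW is computed on the filtered central second (the study does not say
whether filtering preceded the ACF; we filter first).

The fine-scale peri-seizure profile uses 5-s windows around onsets. The
study's "half a second overlap between windows" is read literally
(consecutive windows share 0.5 s, i.e. a 4.5-s step); `overlap = "step"`
selects the alternative 0.5-s-step reading, and both are tested. The
normalization baseline is the 5 min before onset by default (the methods
text says 5 min, a figure caption says 1 min; `baseline_min = 1` selects
the latter).

# Rhythms, phases and missing data

Each biomarker series is decomposed with *causal* moving averages: the long
cycle is a 2-day (1440-sample) MA; the residual smoothed by a 20-sample
(40-min) MA is the short cycle. Warm-up samples average whatever history
exists and are flagged, rather than discarding the first two days. Note a
structural property of causal decomposition: the 2-day MA lags by about one
day, so the residual -- hence the short cycle -- retains lag-induced leakage
of multi-day periods (about 45% amplitude for a 10-day cycle). The
forward-backward ("anti-causal") variant used by Method M1 is zero-phase
and suppresses that leakage below 15%. This is why the within-sample and
pseudoprospective analyses legitimately see different short cycles.

Gaps shorter than 2 h (60 samples) are filled with Gaussian noise matched
to the channel's non-missing mean and SD (per channel, not pooled across
channels); gaps of 60 samples or more stay missing, are noise-filled only
transiently so the Hilbert transform is computable, and invalidate phases
within 2 h on either side. The same exclusion is applied at record
boundaries (conservative; the study states it only around dropouts), except
at Method M2's leading edge, where the newest sample *is* the scoring
sample and exclusion would empty the forecast. Gap fills are
seed-deterministic per gap-start index, so truncating a record never
changes fills in the retained prefix -- a property the causality audit
relies on.

Phases come from the argument of the FFT-based analytic signal of the
mean-removed cycles, wrapped to $[-\pi, \pi)$. Dominant periods come from
the magnitude spectrum of the gap-filled, mean-removed raw series; peaks
must exceed `prominence_factor` (default 8) times the median magnitude,
which calibrates to zero false peaks on white noise at these record
lengths while passing any coherent cycle of meaningful amplitude.
Circadian flags cover 0.9--1.1 days, multidien flags 3--30 days.

# Synchrony

The synchronization index is the modulus of the mean unit phasor,
$SI = |\frac{1}{N}\sum e^{i\theta_n}|$. Seizure phases are taken at the
last sample strictly before each onset; if that sample is invalid the
seizure is excluded (not searched backwards) and the exclusion counted.
Histograms use 20 half-open bins on $[-\pi,\pi)$. Channel selection is the
argmax of seizure SI with deterministic lowest-index tie-breaking.
Electrode similarity smooths each channel with the 20-sample causal MA,
removes timestamps missing on any channel (listwise), and averages the
strictly-upper-triangle Pearson correlations.

# Forecasting

`probability_given_phase()` is the empirical table
$P(S|\theta) = S_\theta / N_\theta$ over 20 phase bins. The six
(signal, cycle) tables are multiplied into a probability trace under the
independence assumption. Empty visited bins carry probability 0 by default,
matching the estimator literally.

Thresholds `Th1 <= Th2` (low/medium/high) are found by exhaustive search
over the unique trace values (capped at 500 candidates by even thinning;
the objective is a step function so thinning only coarsens the grid),
maximizing time-in-low x seizures-in-high (C1 x C2). Strict mode (M1)
additionally requires the occupancy ordering C3
(`time_low > time_med > time_high`) and the seizure ordering C4. C4 is
implemented as `seiz_low <= seiz_med <= seiz_high` with strictly more in
high than in low: with a strict-inequality reading, any configuration with
zero seizures in both lower states -- including the canonical
"all seizures in high risk" optimum -- would be infeasible. Levels map as
`p < Th1` low, `p >= Th2` high (right-closed). Ties break toward larger
time-in-low, then larger `Th2`. Risk levels are coded 1/2/3 so a mean
assigned risk of 2.5 means "mostly high".

**Method M1** (within-sample ceiling): zero-phase filtering, tables and
thresholds fitted on all seizures, strict mode with a flagged relaxed
fallback, scored in-sample.

**Method M2** (pseudoprospective): strictly causal. The model is
bootstrapped from the first 10 seizures; each later seizure is scored by
the model frozen since the previous seizure, at the last sample before its
onset, using only data preceding that onset; afterwards tables and
thresholds are refit on the trailing 50-day window (relaxed mode; whether
the study refit thresholds at every seizure or only tables is ambiguous --
both are refit here). Two implementation choices matter and are this
package's own:

* *Edge-stabilized scoring phases.* The FFT Hilbert phase is unreliable in
  the last samples of a record (mean error above 50 degrees in our
  simulations -- three phase bins). Scoring lookups therefore use
  `edge_phase()`: the short cycle is extended one dominant-cycle ahead by a
  least-squares sinusoid (frequency refined around the band-limited FFT
  peak) before the analytic signal is read at the edge; the smooth long
  cycle uses odd point-reflection about the endpoint. Both are
  deterministic functions of the prefix, so causality survives.
* *Online-consistent training.* Each seizure's stored scoring-time phase --
  not its retrospectively re-estimated phase -- populates $S_\theta$ at
  later refits, so the model learns exactly the distribution the scoring
  lookup draws from, and residual estimator jitter becomes part of the
  learned phase spread rather than a systematic train/score mismatch.
* *Laplace smoothing.* The iterative tables hold a few dozen seizures
  while edge phases jitter by a bin or two; a pseudo-count (default 4,
  order of the per-bin jitter mass; chosen in development simulations) is
  added so that spurious empty-bin zeros cannot veto the six-way product.
  M1 keeps the literal zero-empty-bin estimator.

For tractability the M2 phase analysis uses the trailing 60 days of each
prefix (its training window is 50 days) trimmed to an FFT-friendly length;
trimmed head samples are reported invalid.

The **random predictor** estimates the 3x3 transition matrix of the M1
risk-level sequence, simulates independent chains of the same length, and
scores the true seizure times against each chain; the distribution of its
performance products (seizures-in-high x time-in-low) is the chance
benchmark.

# Seizure clusters

Inter-seizure intervals are histogrammed in 1-h half-open bins. A patient
has clusters only if at least five intervals are shorter than one day. The
lead time is 1 day for decay-shaped histograms and the first genuine trough
between the first two peaks for multimodal ones; "genuine" is formalized as
3-bin moving-average smoothing, peaks at least 25% of the modal bin, and a
separating trough below 60% of the smaller peak -- without the prominence
requirements, sampling noise on an exponential decay constantly fakes a
second mode. Ambiguous shapes fall back to 1 day with a warning. Profiles
of ACFW and variance over 4 days after each lead seizure are averaged with
standard errors on the highest-SI channel, alongside a 2-h moving sum of
follow-on seizures.

# Scaling of the acceptance experiments

The study's headline numbers come from multi-year clinical recordings that
are not publicly deposited, so acceptance is property-based on synthetic
records, scaled to desktop minutes: fold-sweep records are 30 days, rhythm
recovery uses 60 days, and the forecasting experiments use 75-day
single-channel records with roughly 0.6 seizures/day (about 45 per record,
about 30 in each 50-day training window). Under this stated world both M1
and M2 beat the 97.5th percentile of the random predictor in essentially
every seed. The pseudoprospective mean assigned risk level sits near the
paper's 2.5 convention; it is sensitive to the short-cycle phase jitter
that causal edge estimation cannot remove, and grows with record length
and seizure count (the clinical records behind the original 2.5-or-greater
figure were up to 767 days with up to 545 seizures).

# Known limitations

* The probability model is the independence product; the joint
  distribution $P(S|A_1, A_2)$ is not estimated (there would rarely be
  enough seizures to fill a 20 x 20 joint table).
* Relaxed threshold optimization is separable and monotone, so its optimum
  always collapses the medium band (`Th1 = Th2`); medium occupancy exists
  only under strict mode.
* M2's time-in-level fractions stitch each inter-seizure interval using
  phases computed at the *next* refit, which is mildly anticausal for
  reporting purposes only; per-seizure risk levels -- the quantities under
  the causality audit -- are strictly causal.
* Statistical significance of SI values (e.g. Rayleigh tests) is
  deliberately not computed.
* The serialization helpers write plain-text CSV/JSON; there is no
  HDF5/parquet dependency in the supported environment.
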