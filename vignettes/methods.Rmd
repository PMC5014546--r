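---
title: "Simulating and analysing change detection in temporally structured tone-pip scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing change detection in temporally structured tone-pip scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonescenes)
```

## The problem this package addresses

Listening in natural environments means tracking many concurrent sound
sources and noticing when something new enters the scene. A standard
laboratory model of this situation presents "scenes" of seven or eight
concurrent pure-tone sources, each a train of tone pips at its own carrier
frequency, and asks whether listeners detect the *appearance* of a new
source partway through. The key manipulation is temporal statistics: in
**REG** scenes every source pulses with a fixed tone/silence cycle, so the
scene is fully predictable; in **RAND** scenes each silent interval is drawn
anew from the same distribution, so the envelope statistics match but the
temporal pattern is unpredictable. Behaviourally, appearances in REG scenes
are detected better and faster; neurally, magnetoencephalography (MEG) shows
a larger sustained response to REG scenes emerging a few hundred
milliseconds after scene onset, and an enhanced appearance-evoked response
whose onset depends on whether the listener attends to the scenes.

`tonescenes` implements the complete computational chain of such a study as
tested, reproducible code:

1. **Stimulus synthesis** (`draw_scene_spec()`, `render_scene()`,
   `write_stimulus_set()`) — symbolic scene specifications that render
   deterministically to audio.
2. **Synthetic MEG and behaviour** (`simulate_dataset()`,
   `simulate_behavior()`) — multichannel epoch tensors and trial tables with
   a known, configurable effect structure, so every analysis stage has
   ground truth.
3. **Sensor-space preprocessing** (`lowpass_and_resample()`,
   `epoch_and_baseline()`, `reject_outlier_trials()`, `dss_fit()` /
   `dss_apply()`).
4. **Statistics** (`rms_timecourse()`, `cluster_permutation_test()`,
   `jackknife_onset()`, `jackknife_two_sample_test()`,
   `channel_subset_means()`, `dprime()`, `behavior_summary()`).
5. **Orchestration** (`run_experiment()`), executing all stages from one
   seeded configuration.

Because the original recordings are not public, the statistics operate on
simulated data; the package's purpose is methodological: a faithful,
verifiable implementation of the analysis procedures together with a
generator whose planted effects those procedures should recover.

## Stimulus model

Carriers live on the ERB-number (Cam) scale,
\(E(f) = 21.4\,\log_{10}(0.00437 f + 1)\), the standard Glasberg–Moore
(1990) form. The default pool starts at 200 Hz and steps by 2 ERB until the
next carrier would exceed 2800 Hz, giving 10 carriers (the highest at
about 2746 Hz); the wide spacing minimises energetic masking between
sources. Each scene draws 7 or 8 distinct carriers. Per source, the
tone-pip duration is drawn once from U[22, 167] ms; silent gaps are drawn
once (REG) or per interval (RAND) from U[1, 167] ms. Scenes last
U[2500, 3500] ms; in change scenes the appearing source starts at
U[1000, 2000] ms and the scene ends exactly 1500 ms later, so the
appearance-to-offset interval is constant. Scenes are peak-normalised to
0.9 and shaped with a 30 ms raised-cosine onset/offset ramp.

Choices the stimulus description leaves open, resolved as follows:

* **Ramps.** The 30 ms raised-cosine ramp is applied to the whole scene;
  individual pips carry 5 ms cosine ramps, since a 22 ms pip cannot carry a
  30 ms ramp and unramped pips would click.
* **Source alignment.** Each original source starts with a random offset
  drawn from U[0, tone + first gap], so the source trains are
  desynchronised at scene onset rather than artificially phase-locked. The
  appearing source starts exactly at the appearance time — that onset *is*
  the event of interest.
* **Appearing-source carrier.** Drawn uniformly from the pool entries not
  used by the scene's sources, so the new source never collides with an
  existing carrier.
* **Matched pairs.** A no-change control is derived from a change scene by
  deleting the appearing source and nothing else. Both members are
  normalised by the change member's raw peak, which makes the rendered
  waveforms bit-identical up to the appearance sample — the property the
  evoked-response subtraction logic relies on, and one the test suite
  checks exactly.
* **Appearance times** are rounded to the nearest audio sample so event
  markers are exact.

`auditory_spectrogram()` provides an ERB-channel heterodyne envelope
display for inspection; it is a visualisation aid, not a peripheral model.

## The synthetic MEG generator

Each subject's noiseless evoked response is a sum of components, each an
amplitude × time-course × unit-norm topography term:

* Transient deflections are Gaussian bumps (SD = FWHM / 2.355). The
  scene-locked response carries an early middle-latency deflection (25 ms)
  and M50 / M100 / M200 deflections at 80 / 110 / 200 ms; the
  appearance-locked response carries the early deflection and
  M50 / M100 / M200 at 90 / 150 / 300 ms. The M100 topography has polarity
  opposite to the M50, as in real auditory fields. In the passive group the
  appearance-locked M100 amplitude is zero, mirroring the reported
  attention sensitivity of that component.
* The sustained response is a logistic step that settles by ~300 ms,
  rising through the M200 period. Together with the early deflection and
  the widened M200 this keeps the evoked magnitude above the noise floor
  throughout the epoch — deliberately so; see *Why the evoked response has
  no silent gaps* below.
* Condition effects are multiplicative gains gated in time at the
  group-specific onset: scene-locked REG scenes add 30% of the sustained
  amplitude from 436 ms (passive) / 476 ms (active); appearance-locked
  responses in REG scenes gain +22% from 87 ms (passive) / 142 ms
  (active). The gate rises over 2 ms centred on the onset, so REG and RAND
  responses are *identical* before the injected latency and the gain is
  complete at the first sample after it. Because the passive onset precedes
  the M50 peak and the active onset follows it, the "+22% M50 in the
  passive group only" pattern emerges from a single mechanism.
* The appearing source's own regularity has no planted MEG effect (only a
  behavioural detection-time advantage), matching the reported null.

Sensor topographies are smooth bilateral source/sink (dipolar) fields on a
sunflower-packed planar array; 274 channels by default, 32 in the fast
profile. Trials add noise with three ingredients: 20 AR(1) sources
(ρ = 0.95, approximating the low-frequency-dominated spectrum of MEG
noise) mixed through smooth spatial maps, an independent per-sensor white
floor, and a 2% fraction of trials scaled ×10 to emulate artefact epochs.
Between subjects, amplitudes scale by a lognormal gain (20%) and component
latencies shift by Gaussian jitter (SD 10 ms); the *effect-onset* latencies
are treated as group-level properties and are not jittered, because they
are the quantities whose recovery the analysis is assessed on. Simulation
is generated directly at the 250 Hz analysis rate; the high-rate
acquisition path exists only as the filter/resampling operators, which the
tests exercise on synthetic high-rate signals.

### Why the evoked response has no silent gaps

The onset-latency criterion below thresholds the REG−RAND difference
against baseline variability. The RMS of a sensor array self-averages:
where a strong common (condition-independent) signal \(S\) is present,
noise-induced RMS fluctuations shrink by roughly \(\sigma / S\); where the
evoked response is exactly zero they equal the baseline fluctuations. A
mean + 3 SD threshold estimated from 50 (autocorrelated) baseline samples
then false-alarms with ~15% probability somewhere in a signal-free search
region — independent of the noise scale, so no SNR makes it vanish. Real
onset analyses inherit this liberality; a generator meant to validate the
estimator must therefore keep common evoked signal throughout the search
window. That is why the component set includes the early middle-latency
deflection and why the sustained response bridges the M200. Similarly, the
smooth noise subspace is orthogonalised against the component topographies
(the white sensor floor still overlaps them): with fully overlapping
smooth noise, the RMS cross-term makes signal-period fluctuations ~1.4×
the baseline's, and the criterion false-alarms at any SNR.

### Behaviour

Hits are binomial with detection probability 0.85 (REG) / 0.672 (RAND) —
group mean 0.761 — and false alarms binomial at 0.0625 on no-change
trials. Detection times are Gaussian (SD 80 ms) around 650 ms, 40 ms
faster in REG scenes and a further 27 ms faster when the appearing source
is itself regular, truncated below at 100 ms. Subjects share a
logit-normal shift of detection probability and a Gaussian shift of mean
detection time. Trial counts default to 96 change trials per design cell
and 192 no-change trials per scene structure (8 blocks × 96 trials, half
of them changes).

## Preprocessing

* **Filtering** — `lowpass_and_resample()` uses a zero-phase linear-phase
  FIR low-pass (windowed-sinc, centred convolution with reflection
  padding) followed by decimation, or polyphase resampling for non-integer
  rate ratios. The FIR form was chosen over a forward–backward Butterworth
  because a 4th-order zero-phase Butterworth at 30 Hz attenuates 24 Hz
  (0.8 × cutoff) to ~0.86 — it cannot be simultaneously flat to 1% in the
  passband and >20 dB down at twice the cutoff, which the FIR design
  achieves comfortably.
* **Epoching** — windows are half-open `[t0, t1)`, so (−200, 800) ms at
  250 Hz is exactly 250 samples and (−200, 400) ms exactly 150. The mean
  over the half-open baseline is subtracted per channel and trial;
  baselining precedes rejection.
* **Outlier rejection** — the deviation of a trial is its RMS distance
  (over channels × samples) from the across-trial mean; trials more than
  3 SD above the mean score are dropped in a single pass. The metric is a
  trial-level summary rather than per-channel because the artefacts being
  modelled (movement, dental work) are global; the decision is scale
  invariant.
* **DSS** — denoising source separation whitens by PCA on the pooled
  trial covariance (discarding eigenvalues < 1e−6 of the largest) and
  eigendecomposes the covariance of the trial average in whitened space.
  Eigenvalues are trial-to-trial reproducibility ratios in [0, 1]: 1 for
  noiseless data, ≈ 1/n for pure noise. The model is fitted per subject on
  the scene-onset epochs (−200 to 800 ms) and applied to both scene- and
  appearance-locked epochs; the two most reproducible components are kept
  and projected back to sensor space. Projection is idempotent and is the
  identity at full rank — both are tested.

## Statistics

* **RMS time-course** — \(\sqrt{\text{mean}_c\, x^2(c,t)}\), a
  polarity-free magnitude summary.
* **Cluster-based permutation test** — per-sample paired (or two-sample)
  t statistics; samples beyond the two-tailed critical value at the
  height threshold p < 0.05 form temporally contiguous clusters summarised
  by their *mass* (sum of |t|); family-wise error is controlled by the
  permutation distribution of the maximum cluster mass (5000 iterations at
  full scale), with per-subject sign flips for paired designs and label
  shuffles for two-sample ones. Mass was chosen as the cluster statistic
  because it is the common default and dominates size for broad effects;
  positive and negative clusters are pooled in the null; Monte-Carlo
  p-values carry the +1 correction so they are never zero. For paired
  designs with ≤ 20 subjects the null can instead be enumerated exactly
  over all \(2^n\) sign patterns, which the tests compare against an
  independent enumeration oracle.
* **Jackknife onset latency** — for each leave-one-subject-out grand
  average of the REG−RAND difference, the onset is the first post-zero
  sample whose magnitude exceeds the mean + 3 SD of the baseline
  (−200 to 0 ms) magnitudes. The subsample SD underestimates
  between-subject variability by a factor n−1, so the reported corrected
  SE is `sd(latencies) * (n-1) / sqrt(n)`, and the two-group comparison
  inflates each group's sum of squares by \((n_g-1)^2\) with
  df = n₁ + n₂ − 2. Subsamples that never cross flag the estimate
  incomplete rather than erroring; the group test requires complete
  estimates.
* **Channel-subset analysis** — channels are ranked by their mean signal
  in the M50 window (72–112 ms) on the condition-pooled group average; the
  20 most positive and 20 most negative channels are averaged per subject
  with polarity preserved, separating overlapping components of opposite
  polarity that RMS confounds.
* **Behaviour** — d′ = Φ⁻¹(hit rate) − Φ⁻¹(false-alarm rate) with rates
  clamped to [1/(2N), 1 − 1/(2N)] (extreme rates stay finite; the clamping
  rule is the standard correction, chosen because the study reports only
  non-extreme group means). Condition summaries carry within-subject SEs
  (subject-mean centring with the Morey correction), and 2 × 2
  repeated-measures ANOVAs use the classical sums-of-squares decomposition
  via `stats::aov` — with two-level factors no sphericity correction is
  needed.

## Problem sizes and profiles

The `fast` profile (32 channels, 6 subjects per group, 16 trials per cell,
200 permutations) runs the full pipeline in seconds and is what the
pipeline tests use. The `paper` profile keeps the study-scale design (274
channels, 14 passive / 13 active subjects, 96 trials per cell, 5000
permutations). The parameter-recovery simulations in the test suite use
the full subject counts (14/13) with the 32-channel array, 192 pooled
appearance trials (two appearing-source cells of 96) or 96 scene trials
per condition, and 20 replicates; the false-positive calibration uses 200
null replicates of 10 subjects with 500 permutations. These sizes were
chosen as the smallest at which the estimators operate in their intended
regime.

## What the simulations do and do not show

The generator reproduces the *structure* of the study's data — group
sizes, condition design, component latencies and topography polarity,
effect onsets and magnitudes, hit/false-alarm rates — with planted ground
truth, which is exactly what is needed to verify the analysis code. It
does not model head geometry or leadfields, eye or cardiac artefacts,
induced (non-phase-locked) oscillatory activity, or between-subject
topography variability, and its noise is Gaussian. Passing tests therefore
demonstrate that the procedures are implemented correctly and are
calibrated and sensitive under a realistic effect structure — not that the
original biological findings are reproduced; the study's printed
data-dependent statistics (specific F and t values, the 289/412 ms scene
onset estimates) are not reproduction targets. Source-space analysis
(forward modelling, inversion, source statistics) is out of scope.

## Numerical conventions

Half-open windows everywhere (sample counts are exact); seeds are
mandatory in the pipeline, and one master seed spawns per-stage child
seeds through a fixed hash, so stimulus and noise streams are independent
but reproducible; WAV output is deterministic to the byte; permutation
p-values are never 0; DSS discards covariance eigenvalues below 1e−6 of
the largest; baseline means after correction are zero to machine
precision. Degenerate inputs (all trials rejected, criterion never
crossed, zero-variance jackknife with unequal means) are flagged or raise
informative errors rather than returning silent nonsense.
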