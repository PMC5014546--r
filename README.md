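# tonescenes

Synthesis and statistical analysis of multi-source tone-pip "scenes" for
auditory change-detection experiments, with a synthetic MEG/behaviour
generator that plants a known effect structure so the full analysis chain
can be validated end to end.

## What it does

Listeners monitoring a crowd of concurrent sounds are better at noticing a
new source appearing when the scene's temporal statistics are regular.
`tonescenes` implements the complete computational chain of such a study:

* **Stimuli** — scenes of 7–8 concurrent pure-tone sources with carriers
  spaced 2 ERB apart on the ERB-number scale
  (`E(f) = 21.4 log10(0.00437 f + 1)`) between 200 and 2800 Hz. Sources
  are tone-pip trains (tone U[22, 167] ms, gaps U[1, 167] ms) with fixed
  (REG) or randomly varying (RAND) silent intervals; change scenes add an
  appearing source at U[1000, 2000] ms with scene offset fixed 1500 ms
  later. Matched change/no-change pairs render bit-identically before the
  appearance. Output: 44.1 kHz WAV plus JSON/CSV sidecars.
* **Synthetic MEG** — channels × time × trials epoch tensors for passive
  (n = 14) and active (n = 13) listener groups with M50/M100/M200 and
  sustained components, spatially structured AR(1) noise, outlier trials,
  and the study's effect structure planted: a REG > RAND sustained gain
  from 436/476 ms (passive/active), a +22% appearance-evoked gain from
  87/142 ms, no M100 in passive listeners.
* **Preprocessing** — zero-phase low-pass at 30 Hz with resampling to
  250 Hz, half-open epoching with baseline correction, 3-SD outlier-trial
  rejection, and DSS denoising (two most reproducible components, fitted
  on scene-onset epochs).
* **Statistics** — sensor RMS time-courses; cluster-based permutation
  tests (per-sample paired t, cluster mass, max-statistic FWE control,
  optional exact sign-flip enumeration); jackknife onset-latency
  estimation with the (n−1) SE correction and the jackknife-adjusted
  two-sample test; polarity-preserving channel-subset analysis; d′ with
  1/(2N) clamping and 2×2 repeated-measures ANOVA.
* **Pipeline** — `run_experiment()` runs behaviour → simulation →
  preprocessing → statistics from one seeded, validated configuration and
  emits a machine-readable report.

## Worked example

```r
library(tonescenes)

# A matched stimulus pair
spec <- draw_scene_spec(seed = 42, scene_regularity = "REG")
spec
#> Scene: REG, 7 sources, 3415 ms, regular source appears at 1914.8 ms
pair <- render_pair(make_matched_pair(spec))
write_wav(pair$change, "scene_change.wav")

# End-to-end simulated experiment (fast profile: 32 channels,
# 6 subjects/group, 200 permutations)
report <- run_experiment(default_config("fast", seed = 3))
report
```

The report prints, per group, the cluster-level statistics and jackknife
onset estimates. With seed 3 the passive group shows an FWE-significant
REG > RAND cluster over the sustained scene-evoked response spanning
436–796 ms (cluster mass 1210.5, p = 0.035) and an appearance-evoked
cluster over the M50 at 88–112 ms (mass 72.1, p = 0.035); the active
group's scene effect instead spans 476–796 ms (mass 1180.3, p = 0.020)
and its first appearance-evoked cluster sits at 144–192 ms (mass 167.9,
p = 0.030) — the planted attention-dependent latency shift. The
behavioural summary shows the REG > RAND d′ advantage (scene main effect
F(1, 5) = 20.8, p = 0.006 at this profile; appearing-source structure
F(1, 5) = 0.07, n.s.) and the ~27 ms detection-time advantage for regular
appearing sources. `write_report(report, "out/")` saves the JSON/CSV
artefacts. (At this deliberately small fast profile the jackknife onset
SEs are wide; the parameter-recovery simulations in the test suite use
the full 14/13-subject design.)

A thin command-line front end is included:

```sh
Rscript inst/cli/tonescenes-cli.R synth-stimuli --out stim/ --seed 1
Rscript inst/cli/tonescenes-cli.R run-all --out results/ --seed 1 --profile fast
```

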