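# gazebias

Analysis of covert spatial attention *inside* visual working memory, from two
complementary physiological markers:

* **Microsaccade direction biases** — fixational saccades (< 2°) detected
  with a velocity-threshold method occur more often toward the memorized
  location of the attended item. The marker is the toward-minus-away saccade
  rate (Hz) over time.
* **Posterior alpha (8–12 Hz) lateralization** — alpha power decreases over
  the hemisphere contralateral to the attended memorized location, indexed as
  ((contra − ipsi)/(contra + ipsi)) × 100.

The package is written for researchers studying retrocue working-memory
tasks: items are encoded left and right, a central probabilistic retrocue
orients attention within memory, and a central memory test prompts report —
so any lateralized modulation after cue or test reflects orienting *in mind*,
not stimulus processing. It implements the complete chain: blink rejection
and event-locked epoching; saccade detection (5× median velocity threshold on
7 ms Gaussian-smoothed horizontal velocity, 100 ms refractory), toward/away
labelling, sliding-window rate/bias time courses and size-resolved maps;
short-time Fourier spectra (300 ms Hanning, 10 ms steps, 2–40 Hz) and
lateralization indices/topographies; onset/offset latency estimation by
jackknife 50 %-of-peak and fractional-area (25 %/75 % above a 0.3 Hz floor)
methods; cluster-based permutation inference (sum-of-t cluster mass, max-mass
null, 10,000 permutations); JZS Bayes factors; repeated-measures ANOVA with
linear trend; and trial-count-matched sub-sampling controls.

Because recorded data are not required to validate any of this, the package
ships a synthetic session generator (`sim_config()`, `simulate_session()`)
that emulates the task: 1000 Hz gaze with fixational drift and blink
artifacts, a microsaccade point process whose toward-probability is
transiently elevated after the cue (scaled by cue reliability 100/80/60 %)
and after the test (prolonged by 100 ms on invalid trials), lateralized alpha
oscillations, and von Mises / lognormal behavior. Every estimator is tested
by recovering the generator's configured truth.

## Worked example

```r
library(gazebias)

cfg <- sim_config(trials_per_block = 250, reliabilities = "80", seed = 11)
ses <- simulate_session(cfg, subject = 1)

rec <- mask_blinks(ses$gaze)                       # zero-run blink rejection
ep  <- epoch_gaze(rec, ses$meta$cue_onset, "cue")  # -200..1500 ms epochs
ev  <- label_direction(detect_saccades_epochs(ep), ses$meta, "cued")
rc  <- rate_timecourse(ev, nrow(ses$meta), ep$time)

mean(rc$bias[rc$time >= 200 & rc$time <= 600])
#> [1] 0.751
```

`0.751` is the mean saccade bias (toward minus away, in Hz) in the a-priori
200–600 ms post-cue window: saccades during orienting are substantially more
frequent toward the cued item's memorized side than away from it. Detector
performance against the generator's injected ground truth at the same
settings (250 trials, default drift noise): hit rate 93.9 % for saccades
≥ 0.3° within ±10 ms, false alarms 0.127 Hz on saccade-free drift.

For latencies:

```r
t <- 0:900
tri <- approx(c(0, 200, 400, 600, 900), c(0, 0, 1, 0, 0), xout = t)$y
peak_fraction_latency(t, tri)[c("onset", "offset")]
#> $onset  [1] 300
#> $offset [1] 500
```

A full synthetic study — simulate, preprocess, analyze, test — is one call:

```r
bundle <- run_pipeline(sim_config(seed = 1), n_perm = 2000)
write_report(bundle, "results/")
```

The bundle contains, per reliability block, cue-locked bias and alpha
time courses with one-sample cluster tests, test-locked valid/invalid biases
with paired cluster tests, jackknife and fractional-area latency
comparisons (the configured 100 ms invalid-trial prolongation is recovered
as ≈ 90–96 ms offset shifts with no onset difference), sub-sampling
controls, and behavioral summaries with ANOVA/trend/Bayes-factor tests.

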