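---
title: "Methods: gaze and EEG markers of attentional orienting in working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze and EEG markers of attentional orienting in working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazebias)
```

## The scientific problem

When people hold several visual items in working memory, a probabilistic
retrocue lets them orient attention *internally* to the item that is likely to
be tested; the eventual memory test can then either confirm that expectation
(valid trials) or violate it (invalid trials), prompting a *re-orienting*
within memory. Two non-invasive markers track where covert attention points
inside the memorized display:

* **Microsaccade direction biases.** Small fixational saccades (< 2 visual
  degrees) occur more often toward the memorized location of the attended
  item. The bias is quantified as the difference between toward- and
  away-saccade rates (Hz) over time.
* **Posterior alpha (8--12 Hz) lateralization.** Alpha power drops over the
  hemisphere contralateral to the attended memorized location. The index
  `((contra - ipsi)/(contra + ipsi)) * 100` is negative when attention is
  deployed to the reference side.

`gazebias` implements the complete analysis chain for both markers, plus the
latency and inference machinery needed to ask *when* re-orienting starts and
ends, and a synthetic session generator so that every stage can be validated
by parameter recovery rather than by eye.

## The synthetic session generator

`sim_config()` fixes the study conditions; `simulate_session()` draws one
subject. The emulated task: two lateral items are encoded, a central retrocue
(onset 1000 ms into each 4 s trial) indicates the likely test item, and a
central memory test follows 1500 ms later. Four block types differ in cue
reliability: imperative 100%, informative 100%, 80%, and 60%, with 250 trials
per block and deterministic validity counts (an 80% block of 250 trials has
exactly 200 valid and 50 invalid trials, in shuffled order).

Component models, and why they look the way they do:

* **Fixational drift** is a mean-reverting random walk: drift *velocity* is an
  AR(1) process (RMS 0.5 deg/s per axis, 20 ms correlation time) and position
  relaxes toward fixation with a 200 ms time constant. Physiological drift is
  slow and bounded; velocity-correlated drift also gives the detector a
  realistic noise floor (white positional jitter at 1000 Hz would not).
* **Microsaccades** form an inhomogeneous Poisson process (thinning) at a
  1.5 Hz base rate with a 100 ms refractory period. The base rate is a free
  parameter of the generator chosen from typical fixational statistics, not
  an empirical value from any one dataset. Amplitudes are lognormal
  (median 0.5 deg, truncated to 0.1--3 deg), so most events are in the
  microsaccade range (< 2 deg). Each saccade displaces gaze along a 20 ms
  sigmoid; displacements decay slowly (800 ms) so gaze re-centers, as real
  fixation does.
* **Direction bias.** The probability that an event goes toward the reference
  side is `0.5 + gain * w(t)`, where `w(t)` is a bump with a raised-cosine
  rise (100 ms), a flat plateau, and a raised-cosine fall (100 ms)
  (`bias_profile()`). The flat plateau is deliberate: extending the plateau by
  `invalid_offset_extension` (100 ms by default) moves the 50%-of-peak offset
  latency by exactly that amount, so latency recovery has a well-defined
  ground truth. A pure raised cosine would convert a duration extension into
  only 3/4 of an offset shift, leaving the generator's truth ambiguous. After
  the cue the reference is the cued side, with gains graded by reliability
  (0.40, 0.40, 0.32, 0.24 for imperative-100/100/80/60); after the test the
  reference is the tested side (gain 0.35), and invalid trials extend the
  plateau rather than delaying the onset -- re-orienting that is prolonged,
  not postponed.
* **Blinks** are zero-runs (the way trackers report signal loss) at 0.1 Hz,
  100 ms long. In `clean_blinks` mode they are never placed where their
  padded extent would touch the 0--900 ms post-test window.
* **EEG** is simulated at 200 Hz (all analysis frequencies are at or below
  40 Hz, so Nyquist is comfortable and synthetic studies stay tractable): a
  10 Hz oscillation with trial- and channel-random phase plus AR(1)
  background noise (`noise_ar` 0.95, innovation SD 1). From 250 ms after the
  locking event, lateral-channel amplitudes are scaled so the *signal* power
  lateralization equals the configured percentage (`sqrt(1 +/- L/100)` on
  amplitude). Configured values are graded -20/-20/-15/-10 percent across
  reliabilities. Background noise adds equally to both hemispheres and
  therefore dilutes the measured index slightly toward zero; at the default
  signal-to-noise ratio the dilution is well under one percentage point.
* **Behavior.** Reports are the true orientation plus von Mises noise on the
  doubled 180-degree circle (Best--Fisher sampler, `rvonmises()`), with
  concentration 12 (valid) vs 6 (invalid) -- giving mean absolute errors a
  few degrees apart, as typical validity effects are. RTs are lognormal with
  a validity-dependent location (about 1.0 s valid vs 1.15 s invalid).

What the generator does **not** emulate: pupil dynamics, EEG artifacts
(ocular or muscular), volume-conducted topographies beyond a hemisphere
label, oculomotor main-sequence kinematics beyond a fixed 20 ms waveform, or
any between-subject heterogeneity in effect size. Passing recovery tests
therefore shows that the estimators are correct and calibrated under the
assumed signal structure -- not that real recordings meet those assumptions.

## Saccade analysis

Detection follows the velocity-threshold recipe: horizontal velocity as the
absolute distance of consecutive samples, a Gaussian-weighted moving average
over a 7 ms window (we take sigma = window/5, the convention of the common
MATLAB smoother; configurable), a threshold at five times the median smoothed
velocity of the epoch (median over valid samples), a 100 ms onset refractory,
and pre/post positions averaged over -50--0 ms and +50--100 ms around the
crossing. Horizontal-only velocity is the default since the items are
arranged horizontally; a caller can smooth/decide on 2-D input by passing the
Euclidean channel instead. Zero-displacement events are direction-undefined
and dropped. Note one numerical consequence of the *centered* smoothing
kernel: for a step-like saccade the first supra-threshold sample can precede
the physical step by up to half the kernel (3 ms). Detection accuracy is
validated by injection-recovery (at least 90% of injected saccades of 0.3 deg
or more are found within 10 ms, with false alarms under 0.2 Hz on
saccade-free drift).

Rates use a centered 50 ms window sliding in 1 ms steps, counts pooled over
trials and divided by `n_trials * window`; windows truncated at the epoch
edge use the truncated length in the denominator, so the estimator stays
unbiased at the edges. The bias is defined as toward minus away, exactly.
Missing samples contribute no events but trials stay in the denominator (the
simplest convention; a per-window valid-trial denominator would only matter
when blinks are dense).

The size-resolved map (`size_time_map()`) partitions the bias by saccade
magnitude with an explicit overflow bin, so summing over bins always
reproduces the overall curve. `classify_toward_trials()` implements the
first-saccade rule in the a-priori 200--600 ms post-cue window.

## Latency estimation

`peak_fraction_latency()` finds the first time the curve reaches half its
positive peak before the peak and first drops below it after, with linear
interpolation between samples. The peak is the global maximum of the (already
50 ms-smoothed) curve; no extra smoothing is applied. If the curve never dips
below the criterion inside the search window, the window edge is returned.
The default search window is 0--900 ms post test, the full test-locked epoch.

`fractional_area_latency()` accumulates area above a 0.3 Hz noise floor,
treating each sample as spanning `[t, t + dt)` (left-Riemann cumulative
area), and interpolates the times where cumulative area reaches 25% and 75%
of the total. Under this convention the worked example -- a 1.3 Hz rectangle
on [300, 500) ms with a 0.3 Hz floor -- yields exactly 350 and 450 ms.
Curves that never exceed the floor are flagged `zero_area` and excluded from
group tests with a reported count (the most defensible reading of the reduced
degrees of freedom such analyses produce; we do not claim it reproduces any
specific dataset's exclusions).

`jackknife_latency_compare()` computes latencies on leave-one-subject-out
grand averages and rescales the variance of the leave-one-out differences by
`(n-1)^2` (the standard correction for the dependence the subsampling
induces) before the paired t-test. A point worth knowing when interpreting
recoveries: at realistic trial counts the 50%-of-peak offset difference is
slightly *under*-estimated (first noise dip below the criterion ends the
measured bias early, more so in the noisier, smaller condition). The
estimator is unbiased in the large-trial limit -- we verify ~104 ms recovered
for a 100 ms plateau extension at 30k trials -- and the median recovery at
the study's own counts stays within 20 ms of the configured truth.

## Spectral analysis

`stft_power()` slides a 300 ms Hanning taper in 10 ms steps and projects each
windowed segment onto complex exponentials at the requested frequencies
(2--40 Hz in 1 Hz steps by default). Exact DFT projection was chosen over
zero-padded FFT bins because it lands on the 1 Hz grid exactly for any
sampling rate and lets the pipeline restrict computation to the 8--12 Hz band
where only the alpha index is needed; for a sinusoid of amplitude `a` the
estimate at the target frequency is `a^2/2`, verified numerically. Power is
computed per trial and averaged within a trial selection; the lateralization
contrast is a ratio of trial-mean powers (a condition-level contrast), not a
mean of per-trial ratios.

The electrode clusters default to the published definition, which is
asymmetric: the left cluster lists nine electrodes including `O2`, the right
seven. We keep it as printed (`posterior_clusters("printed")`) and provide a
`"symmetric"` variant that moves `O2` to the right cluster. The distinction
matters for recovery: with a hemisphere-defined simulated truth of -20%, the
printed clusters dilute the measured index to about -17.8% (the misplaced
electrode contributes with opposite sign), while the symmetric clusters
recover -20% to within a fraction of a point. Recovery tests therefore use
the symmetric variant; analyses meant to mirror the published setup should
keep the printed default.

## Inference

`cluster_permutation_test()` forms clusters as maximal runs of temporally
adjacent, same-sign t values exceeding the two-sided 0.05 threshold; cluster
mass is the sum of t values; the null is the maximum absolute cluster mass
over random sign flips (one-sample) or condition swaps (paired), with 10,000
permutations by default. Positive and negative clusters are formed separately
but compared against the single max-|mass| null -- the conservative, standard
two-sided construction. P-values include the observed labelling
(`(1 + k)/(n_perm + 1)`), so they are never zero. Validity is checked two
ways: exhaustive enumeration of all 2^6 sign flips at n = 6 matches the
Monte-Carlo estimate, and the family-wise error over 200 null datasets falls
inside the binomial 95% interval around 0.05.

`rm_anova_linear_trend()` wraps the standard within-subject ANOVA and tests
the linear trend with the orthogonal-polynomial contrast per subject.
`jzs_bf01()` integrates the Jeffreys--Zellner--Siow Cauchy-prior Bayes factor
(scale sqrt(2)/2) with adaptive quadrature; `bf01 > 1` favors the null, the
function is strictly decreasing in |t|, and the quadrature is stable to 1e-6
relative under tightened tolerance. `subsample_match()` implements the
trial-count control: valid trials are repeatedly subsampled to the invalid
count (1000 draws by default) and the bias curves averaged.

## Numerical choices and degenerate inputs

* Blink runs are defined by *exactly* zero samples on all recorded channels,
  matching how the generator (and trackers) encode loss; padded by 100 ms.
* Epoch windows are -200..1500 ms (cue) and -200..900 ms (test); epochs may
  overlap; out-of-bounds epochs raise an error naming the trial.
* Zero-variance time points inside the cluster test get undefined t and are
  treated as sub-threshold, with a reported count.
* Identical pairs in a paired t-test are a zero-variance error, not t = 0.
* A flat or non-positive curve has no 50%-of-peak latency (error); a curve
  below the FAL floor is flagged rather than given a latency.
* Latency crossings on sampled jumps land half a sample inside the jump --
  the price of honest linear interpolation.
* All stochastic stages derive their streams from one master seed
  (`derive_seed()`), so stages are reproducible in isolation and identical
  seeds give bit-identical sessions.

## Problem sizes used in the validation suite

The shipped tests validate at the study's own scale where the property
demands it: injection-recovery on 500 trials; rate calibration on 500 trials
of a homogeneous 1.5 Hz process; jackknife recovery on twenty 22-subject
event-level studies per block type; family-wise error on 200 null datasets
(500 permutations each, 12 subjects, 60 time points); alpha recovery on 250
trials; and one full 24-subject, 4-block, 250-trials-per-block end-to-end
study with 2000-permutation cluster tests. The end-to-end study checks the
qualitative pattern the generator is built to produce: reliability-graded
cue-locked bias and alpha lateralization, test-locked toward biases for both
valid and invalid tests in the 80/60 blocks, a valid-vs-invalid difference,
and an offset (not onset) prolongation on invalid trials that survives the
trial-count-matched sub-sampling control.

## Known limitations

* The generator's homogeneous-subject design understates between-subject
  variance; group-level t statistics on synthetic studies are therefore
  larger than typical empirical ones.
* The detector's onset convention (first supra-threshold sample of a
  centered-smoothed velocity) carries a small systematic early shift for
  abrupt steps.
* FAL latencies on single-subject curves from few trials are noisy; the
  group comparison reports but does not reinterpret them.
* The alpha module deliberately omits a surface Laplacian: simulated
  channels are already spatially local, and the transform belongs to
  real-data preprocessing.
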