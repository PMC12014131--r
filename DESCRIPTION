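Package: gazebias
Title: Gaze and EEG Markers of Attentional Orienting in Visual Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of spatial attention shifts within visual working memory
    from eye-tracking and EEG recordings. Implements velocity-threshold
    (micro)saccade detection with toward/away direction labelling, sliding-window
    saccade-rate and direction-bias time courses, size-resolved bias maps,
    posterior alpha-band (8-12 Hz) power lateralization from short-time Fourier
    spectra, onset/offset latency estimation by jackknife 50%-of-peak and
    fractional-area methods, cluster-based permutation inference with sum-of-t
    cluster mass, JZS Bayes factors, repeated-measures trend tests, and
    trial-count-matched sub-sampling controls. Ships a synthetic session
    generator (fixational drift, blink artifacts, cue- and test-locked
    microsaccade direction biases scaled by retrocue reliability, lateralized
    alpha oscillations, and orientation-reproduction behavior) so the complete
    pipeline can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
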