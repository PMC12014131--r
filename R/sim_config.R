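#' Reliability levels used throughout the package
#'
#' The four block types of the task: an imperative 100% reliable cue
#' (report is forced through the cue), an informative 100% reliable cue,
#' and informative 80% and 60% reliable cues.
#' @keywords internal
RELIABILITY_LEVELS <- c("imp100", "100", "80", "60")

.validity_fraction_for <- c(imp100 = 1.0, "100" = 1.0, "80" = 0.8, "60" = 0.6)

#' Default trial timing (ms from trial start)
#'
#' Encoding display 200 ms, 800 ms delay, 200 ms retrocue, 1300 ms delay,
#' then the central memory test. Cue onset is therefore at 1000 ms and test
#' onset at 2500 ms; each trial spans 4000 ms so that the test-locked
#' analysis window (-200 to +900 ms) plus slack fits inside the trial.
#' @keywords internal
.trial_layout <- function() {
  list(cue_onset = 1000, test_onset = 2500, trial_len = 4000)
}

#' Build a synthetic-session configuration
#'
#' Collects every parameter of the synthetic study generator: block structure
#' and cue reliabilities, gaze sampling and fixational-drift parameters, the
#' microsaccade point process and its cue-/test-locked direction biases,
#' blink artifacts, lateralized alpha oscillations, and behavioral report
#' parameters. Defaults reproduce the study conditions the analyses assume:
#' four blocks (imperative 100%, 100%, 80%, 60% reliable cues) of 250 trials,
#' 1000 Hz gaze, and graded bias/lateralization gains across reliabilities.
#'
#' @param n_subjects number of subjects a multi-subject study simulates.
#' @param trials_per_block trials per reliability block.
#' @param reliabilities character vector of block reliability labels, a subset
#'   of `c("imp100", "100", "80", "60")`. Validity fractions (1, 1, .8, .6)
#'   are implied by the label.
#' @param fs gaze sampling rate (Hz).
#' @param fs_eeg EEG sampling rate (Hz); 200 Hz suffices for the 2-40 Hz
#'   spectral analyses.
#' @param drift fixational drift model: `speed_sd` (deg/s per axis, RMS drift
#'   velocity), `vel_tau` (ms, drift-velocity correlation time), `pos_tau`
#'   (ms, position mean-reversion time towards fixation).
#' @param base_saccade_rate baseline microsaccade rate (Hz).
#' @param main_sequence saccade amplitude model: lognormal `amp_meanlog`,
#'   `amp_sdlog` truncated to `amp_range` (degrees); `vpeak_slope` (1/ms-ish
#'   scale linking amplitude to peak velocity through the 20 ms waveform).
#' @param cue_bias cue-locked toward-direction bias bump: `onset` (ms after
#'   cue), cosine `rise`, flat `plateau`, cosine `fall` (ms), and a named
#'   `gain` vector per reliability (added probability of a toward saccade at
#'   the bump peak, graded 100 > 80 > 60).
#' @param test_bias test-locked bump, same shape parameters, single `gain`,
#'   plus `invalid_offset_extension` (ms added to the plateau on invalid
#'   trials -- the re-orienting prolongation the latency analyses recover).
#' @param blink blink artifacts: `rate` (Hz), `duration` (ms). Blinks are
#'   encoded as zero-valued samples, as eye trackers report them.
#' @param alpha lateralized oscillation: `freq` (Hz), `base_amp` (arbitrary
#'   microvolt-scale units), AR(1) background noise `noise_ar`/`noise_sd`,
#'   named `lateralization_pct` per reliability (negative = lower power
#'   contralateral to the attended side), `onset` (ms post event).
#' @param behavior report model: von Mises concentrations `kappa_valid`,
#'   `kappa_invalid` on the doubled 180-degree orientation circle, and
#'   lognormal RT parameters (`rt_meanlog_valid`, `rt_meanlog_invalid`,
#'   `rt_sdlog`; seconds scale).
#' @param clean_blinks if TRUE, blinks are never placed so that their padded
#'   extent intersects the 0-900 ms post-test analysis window.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(trials_per_block = 10, reliabilities = "80")
#' @export
sim_config <- function(n_subjects = 24,
                       trials_per_block = 250,
                       reliabilities = RELIABILITY_LEVELS,
                       fs = 1000,
                       fs_eeg = 200,
                       drift = list(speed_sd = 0.5, vel_tau = 20, pos_tau = 200),
                       base_saccade_rate = 1.5,
                       main_sequence = list(amp_range = c(0.1, 3),
                                            amp_meanlog = log(0.5),
                                            amp_sdlog = 0.6,
                                            vpeak_slope = 3),
                       cue_bias = list(onset = 100, rise = 100, plateau = 200,
                                       fall = 100,
                                       gain = c(imp100 = 0.4, "100" = 0.4,
                                                "80" = 0.32, "60" = 0.24)),
                       test_bias = list(onset = 200, rise = 100, plateau = 150,
                                        fall = 100, gain = 0.35,
                                        invalid_offset_extension = 100),
                       blink = list(rate = 0.1, duration = 100),
                       alpha = list(freq = 10, base_amp = 10, noise_ar = 0.95,
                                    noise_sd = 1,
                                    lateralization_pct = c(imp100 = -20,
                                                           "100" = -20,
                                                           "80" = -15,
                                                           "60" = -10),
                                    onset = 250),
                       behavior = list(kappa_valid = 12, kappa_invalid = 6,
                                       rt_meanlog_valid = log(1.0),
                                       rt_meanlog_invalid = log(1.15),
                                       rt_sdlog = 0.25),
                       clean_blinks = FALSE,
                       seed = 1L) {
  reliabilities <- as.character(reliabilities)
  bad <- setdiff(reliabilities, RELIABILITY_LEVELS)
  if (length(bad)) {
    stop("invalid reliability label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(RELIABILITY_LEVELS, collapse = ", "), ")")
  }
  if (fs <= 0) stop("fs must be positive")
  if (trials_per_block < 1) stop("trials_per_block must be >= 1")
  stopifnot(base_saccade_rate >= 0,
            all(cue_bias$gain >= 0), test_bias$gain >= 0)
  if (is.null(names(cue_bias$gain)) ||
      !all(reliabilities %in% names(cue_bias$gain))) {
    stop("cue_bias$gain must be named with every reliability in use")
  }
  if (!all(reliabilities %in% names(alpha$lateralization_pct))) {
    stop("alpha$lateralization_pct must be named with every reliability in use")
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_block = as.integer(trials_per_block),
              reliabilities = reliabilities,
              validity_fraction = .validity_fraction_for[reliabilities],
              fs = fs, fs_eeg = fs_eeg, drift = drift,
              base_saccade_rate = base_saccade_rate,
              main_sequence = main_sequence,
              cue_bias = cue_bias, test_bias = test_bias,
              blink = blink, alpha = alpha, behavior = behavior,
              clean_blinks = isTRUE(clean_blinks),
              layout = .trial_layout(),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  subjects:", x$n_subjects,
      " trials/block:", x$trials_per_block, "\n")
  cat("  blocks:", paste(x$reliabilities, collapse = ", "), "\n")
  cat("  gaze fs:", x$fs, "Hz   eeg fs:", x$fs_eeg, "Hz\n")
  cat("  base saccade rate:", x$base_saccade_rate, "Hz\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Posterior electrode clusters for the lateralization analyses
#'
#' Returns the left/right posterior electrode groupings over which alpha
#' power is averaged before the lateralization contrast. The `"printed"`
#' variant is the cluster definition as published (note the asymmetry: the
#' left cluster lists nine electrodes including "O2", the right cluster
#' seven); the `"symmetric"` variant moves O2 to the right cluster, giving
#' mirror-image eight-electrode clusters. The symmetric variant is the one
#' under which a hemisphere-defined simulated lateralization is exactly
#' recoverable; see the methods vignette.
#'
#' @param variant `"printed"` (default) or `"symmetric"`.
#' @return list with character vectors `left` and `right`.
#' @export
posterior_clusters <- function(variant = c("printed", "symmetric")) {
  variant <- match.arg(variant)
  if (variant == "printed") {
    list(left  = c("O1", "PO7", "PO3", "P9", "P7", "P5", "P3", "P1", "O2"),
         right = c("PO8", "PO4", "P10", "P8", "P6", "P4", "P2"))
  } else {
    list(left  = c("O1", "PO7", "PO3", "P9", "P7", "P5", "P3", "P1"),
         right = c("O2", "PO8", "PO4", "P10", "P8", "P6", "P4", "P2"))
  }
}

#' Default simulated EEG montage
#'
#' The union of both posterior clusters plus four midline electrodes.
#' Hemisphere assignment follows the 10-20 convention: odd digits left,
#' even digits right, trailing "z" midline.
#' @return character vector of channel labels.
#' @export
default_montage <- function() {
  c("O1", "PO7", "PO3", "P9", "P7", "P5", "P3", "P1",
    "O2", "PO8", "PO4", "P10", "P8", "P6", "P4", "P2",
    "Oz", "POz", "Pz", "Cz")
}

#' @keywords internal
channel_hemisphere <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  hemi <- ifelse(grepl("z$", labels, ignore.case = TRUE), "mid",
                 ifelse(num %% 2L == 1L, "left", "right"))
  hemi[is.na(num) & !grepl("z$", labels, ignore.case = TRUE)] <- "mid"
  hemi
}
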