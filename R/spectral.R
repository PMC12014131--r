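#' Short-time Fourier power of EEG epochs
#'
#' Sliding 300 ms Hanning-tapered window advanced in 10 ms steps; power is
#' estimated at the requested frequencies by exact discrete Fourier
#' projection (complex-exponential dot products), so the 1 Hz frequency
#' grid is hit exactly regardless of window length. Power is computed per
#' trial and averaged across the selected trials. Windows that would extend
#' beyond the epoch are dropped.
#'
#' @param epochs an `eeg_epoch_set` (see [simulate_eeg_epochs()]).
#' @param freqs frequencies in Hz (default 2:40).
#' @param trials optional trial indices to average over (default all).
#' @param win_ms taper length in ms (default 300).
#' @param step_ms window step in ms (default 10).
#' @return object of class `tfr`: list(power = channels x freqs x times
#'   array, freqs, times (window centers, ms), channels, n_trials).
#' @export
stft_power <- function(epochs, freqs = 2:40, trials = NULL,
                       win_ms = 300, step_ms = 10) {
  stopifnot(inherits(epochs, "eeg_epoch_set"))
  fs <- epochs$fs
  if (fs < 2 * max(freqs)) {
    stop("sampling rate ", fs, " Hz too low for ", max(freqs), " Hz")
  }
  time <- epochs$time
  n_time <- length(time)
  win_n <- round(win_ms * fs / 1000)
  if (win_n %% 2 == 0) win_n <- win_n + 1
  if (win_n > n_time) stop("epoch shorter than the taper window")
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[2])
  half <- (win_n - 1) / 2
  centers_idx <- seq(half + 1, n_time - half,
                     by = max(1L, round(step_ms * fs / 1000)))
  times <- time[centers_idx]
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, win_n - 1) / (win_n - 1)))
  tsec <- (seq_len(win_n) - 1) / fs
  # projection matrix: win_n x n_freq, taper folded in
  proj <- exp(-2i * pi * outer(tsec, freqs)) * taper
  amp_scale <- 2 / sum(taper)
  n_ch <- dim(epochs$data)[1]
  pw <- array(0, dim = c(n_ch, length(freqs), length(centers_idx)),
              dimnames = list(epochs$channels, freqs, NULL))
  for (c in seq_len(n_ch)) {
    X <- epochs$data[c, trials, , drop = FALSE]
    dim(X) <- c(length(trials), n_time)
    for (j in seq_along(centers_idx)) {
      idx <- (centers_idx[j] - half):(centers_idx[j] + half)
      F <- X[, idx, drop = FALSE] %*% proj          # trials x freqs
      pw[c, , j] <- colMeans(Mod(F)^2) * amp_scale^2 / 2
    }
  }
  structure(list(power = pw, freqs = freqs, times = times,
                 channels = epochs$channels, n_trials = length(trials)),
            class = "tfr")
}

#' Alpha-band (8-12 Hz) power from a TFR
#'
#' @param tfr a `tfr` from [stft_power()].
#' @param band frequency band in Hz, inclusive (default c(8, 12)).
#' @return channels x times matrix of band-mean power; `times` attribute
#'   carries the window centers.
#' @export
alpha_power <- function(tfr, band = c(8, 12)) {
  sel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(sel)) stop("TFR does not cover the requested band")
  out <- apply(tfr$power[, sel, , drop = FALSE], c(1, 3), mean)
  rownames(out) <- tfr$channels
  attr(out, "times") <- tfr$times
  out
}

#' Alpha lateralization index time course
#'
#' For each posterior electrode cluster, contrasts trial-averaged alpha
#' power between trials in which the reference memory item was
#' contralateral vs ipsilateral to the cluster:
#' ((contra - ipsi) / (contra + ipsi)) x 100, then averages the two
#' cluster contrasts. Negative values indicate lower power contralateral
#' to the attended side.
#'
#' @param alpha_left,alpha_right channels x times matrices of trial-mean
#'   alpha power for reference-left and reference-right trials (from
#'   [alpha_power()] on the two trial subsets).
#' @param clusters list with `left`/`right` electrode name vectors
#'   (default [posterior_clusters()]).
#' @return object of class `lateralization_timecourse`: data.frame(time,
#'   index) with index in percent.
#' @export
lateralization_timecourse <- function(alpha_left, alpha_right,
                                      clusters = posterior_clusters()) {
  for (side in c("left", "right")) {
    missing_ch <- setdiff(clusters[[side]], rownames(alpha_left))
    if (length(missing_ch)) {
      stop("cluster channels not present: ", paste(missing_ch, collapse = ", "))
    }
  }
  times <- attr(alpha_left, "times")
  cl_mean <- function(alpha, chs) colMeans(alpha[chs, , drop = FALSE])
  # left cluster: contralateral trials are reference-right trials
  contra_l <- cl_mean(alpha_right, clusters$left)
  ipsi_l <- cl_mean(alpha_left, clusters$left)
  contra_r <- cl_mean(alpha_left, clusters$right)
  ipsi_r <- cl_mean(alpha_right, clusters$right)
  if (any(contra_l + ipsi_l <= 0) || any(contra_r + ipsi_r <= 0)) {
    stop("non-positive power: lateralization index undefined")
  }
  idx_l <- (contra_l - ipsi_l) / (contra_l + ipsi_l) * 100
  idx_r <- (contra_r - ipsi_r) / (contra_r + ipsi_r) * 100
  out <- data.frame(time = times, index = (idx_l + idx_r) / 2)
  class(out) <- c("lateralization_timecourse", "data.frame")
  out
}

#' Alpha lateralization from an EEG epoch set
#'
#' Convenience wrapper: splits trials by the reference side, computes
#' trial-mean alpha power per side via [stft_power()] restricted to the
#' alpha band, and returns the cluster-averaged lateralization index time
#' course.
#'
#' @param epochs an `eeg_epoch_set` with `meta`.
#' @param reference `"cued"` or `"tested"`.
#' @param clusters electrode clusters (default [posterior_clusters()]).
#' @param band alpha band in Hz.
#' @param trials optional subset of trials to use.
#' @param ... passed to [stft_power()].
#' @return a `lateralization_timecourse`.
#' @export
alpha_lateralization <- function(epochs, reference = c("cued", "tested"),
                                 clusters = posterior_clusters(),
                                 band = c(8, 12), trials = NULL, ...) {
  reference <- match.arg(reference)
  meta <- epochs$meta
  side <- if (reference == "cued") meta$cue_side else meta$tested_side
  all_tr <- seq_len(dim(epochs$data)[2])
  if (is.null(trials)) trials <- all_tr
  tl <- intersect(trials, all_tr[side == "left"])
  tr <- intersect(trials, all_tr[side == "right"])
  if (!length(tl) || !length(tr)) stop("need trials on both reference sides")
  freqs <- seq(band[1], band[2])
  al <- alpha_power(stft_power(epochs, freqs = freqs, trials = tl, ...), band)
  ar <- alpha_power(stft_power(epochs, freqs = freqs, trials = tr, ...), band)
  lateralization_timecourse(al, ar, clusters)
}

#' Per-electrode lateralization topography
#'
#' Contrasts window-averaged alpha power between attend-left and
#' attend-right trials for every electrode:
#' ((left - right) / (left + right)) x 100.
#'
#' @param alpha_left,alpha_right channels x times trial-mean alpha power for
#'   attend-left / attend-right trials.
#' @param window averaging window in ms (on the `times` attribute).
#' @return named numeric vector, one percentage per electrode.
#' @export
lateralization_topography <- function(alpha_left, alpha_right,
                                      window = c(400, 800)) {
  times <- attr(alpha_left, "times")
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel)) stop("window outside the time axis")
  l <- rowMeans(alpha_left[, sel, drop = FALSE])
  r <- rowMeans(alpha_right[, sel, drop = FALSE])
  (l - r) / (l + r) * 100
}

#' Window-averaged lateralization index
#'
#' @param tc a `lateralization_timecourse` (or any data.frame with `time`
#'   and `index`).
#' @param window ms window, inclusive (default the a-priori 400-800 ms
#'   post-cue window).
#' @return scalar mean index.
#' @export
window_average <- function(tc, window = c(400, 800)) {
  sel <- tc$time >= window[1] & tc$time <= window[2]
  if (!any(sel)) stop("window outside the time axis")
  mean(tc$index[sel])
}
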