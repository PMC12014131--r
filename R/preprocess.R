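#' Construct a gaze recording
#'
#' Continuous eye-tracking samples on a uniform 1 ms grid (1000 Hz default).
#'
#' @param t time axis in ms (monotone, uniform).
#' @param x,y gaze position in visual degrees.
#' @param pupil optional pupil size (arbitrary units).
#' @param fs sampling rate in Hz.
#' @return object of class `gaze_recording`.
#' @export
gaze_recording <- function(t, x, y = NULL, pupil = NULL, fs = 1000) {
  if (!length(t)) stop("empty recording")
  if (length(x) != length(t)) stop("x and t lengths differ")
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)) {
    stop("time axis must be uniform and increasing")
  }
  structure(list(t = t, x = x, y = y, pupil = pupil, fs = fs),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat("<gaze_recording> ", length(x$t), " samples @ ", x$fs, " Hz (",
      round(length(x$t) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Detect blink artifacts as padded zero-runs
#'
#' Eye trackers report lost samples (blinks) as zeros. Every maximal run of
#' samples where all recorded channels are exactly zero is marked, extended
#' by `pad` ms on each side; overlapping padded runs merge into one
#' interval. Marked samples are treated as missing by all downstream
#' analyses.
#'
#' @param rec a [gaze_recording()].
#' @param pad padding in ms on each side of a zero-run (default 100).
#' @return logical mask over samples (TRUE = blink-contaminated).
#' @export
detect_blinks <- function(rec, pad = 100) {
  stopifnot(inherits(rec, "gaze_recording"))
  z <- rec$x == 0
  if (!is.null(rec$y)) z <- z & rec$y == 0
  if (!is.null(rec$pupil)) z <- z & rec$pupil == 0
  z[is.na(z)] <- FALSE
  if (!any(z)) return(rep(FALSE, length(z)))
  pad_n <- round(pad * rec$fs / 1000)
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mask <- rep(FALSE, length(z))
  for (k in which(r$values)) {
    lo <- max(1, starts[k] - pad_n)
    hi <- min(length(z), ends[k] + pad_n)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Apply a blink mask to a recording
#'
#' @param rec a [gaze_recording()].
#' @param mask logical mask from [detect_blinks()]; computed if omitted.
#' @return the recording with masked samples set to NA.
#' @export
mask_blinks <- function(rec, mask = NULL) {
  if (is.null(mask)) mask <- detect_blinks(rec)
  rec$x[mask] <- NA
  if (!is.null(rec$y)) rec$y[mask] <- NA
  if (!is.null(rec$pupil)) rec$pupil[mask] <- NA
  rec
}

#' Epoch window for a locking event
#'
#' Cue-locked epochs span -200 to +1500 ms, test-locked epochs -200 to
#' +900 ms, matching the EEG analysis windows.
#' @param lock `"cue"` or `"test"`.
#' @return numeric length-2 window in ms.
#' @export
epoch_window <- function(lock = c("cue", "test")) {
  lock <- match.arg(lock)
  if (lock == "cue") c(-200, 1500) else c(-200, 900)
}

#' Event-locked epoching of a gaze recording
#'
#' Cuts one row per event from the (blink-masked) recording. Masked samples
#' propagate as NA. Overlapping epochs are permitted.
#'
#' @param rec a [gaze_recording()] (typically after [mask_blinks()]).
#' @param onsets event onset times in ms (same clock as `rec$t`).
#' @param lock `"cue"` or `"test"`; selects the default window.
#' @param window optional custom window c(start, end) in ms relative to onset.
#' @param meta optional per-event metadata carried along (one row per onset).
#' @return object of class `epoch_set`: list(x = trials x time matrix,
#'   y (if present), time, lock, meta).
#' @export
epoch_gaze <- function(rec, onsets, lock = c("cue", "test"), window = NULL,
                       meta = NULL) {
  stopifnot(inherits(rec, "gaze_recording"))
  lock <- match.arg(lock)
  if (is.null(window)) window <- epoch_window(lock)
  step <- 1000 / rec$fs
  time <- seq(window[1], window[2], by = step)
  n_ep <- length(onsets)
  # uniform time axis: locate samples arithmetically
  start_idx <- (onsets + window[1] - rec$t[1]) / step + 1
  cut_one <- function(series) {
    out <- matrix(NA_real_, n_ep, length(time))
    for (i in seq_len(n_ep)) {
      idx <- start_idx[i]
      if (abs(idx - round(idx)) > 1e-6 || idx < 1 ||
          idx + length(time) - 1 > length(rec$t)) {
        stop("epoch window for event ", i, " (onset ", onsets[i],
             " ms) exceeds recording bounds or is off the sample grid")
      }
      idx <- round(idx)
      out[i, ] <- series[idx:(idx + length(time) - 1)]
    }
    out
  }
  x <- if (n_ep) cut_one(rec$x) else matrix(NA_real_, 0, length(time))
  y <- if (!is.null(rec$y)) {
    if (n_ep) cut_one(rec$y) else matrix(NA_real_, 0, length(time))
  }
  structure(list(x = x, y = y, time = time, lock = lock, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$x), " trials x ", ncol(x$x), " samples, ",
      x$lock, "-locked [", min(x$time), ", ", max(x$time), "] ms\n", sep = "")
  invisible(x)
}
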