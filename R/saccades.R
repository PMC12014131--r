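#' Sample-to-sample gaze velocity
#'
#' Velocity as the absolute distance between consecutive gaze positions,
#' in degrees per sample. The first element is 0; a missing position makes
#' both adjacent velocities missing.
#'
#' @param x numeric gaze position series (degrees); may contain NA.
#' @return numeric velocity series of the same length.
#' @export
compute_velocity <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  c(0, abs(diff(x)))
}

#' Gaussian-weighted moving-average smoothing
#'
#' Centered Gaussian kernel over a `window` ms sliding window (rounded to an
#' odd number of samples), with sigma = window / 5 samples. Edge and
#' missing-data handling renormalizes the kernel over the available samples;
#' positions that are themselves missing stay missing.
#'
#' @param series numeric series (may contain NA).
#' @param window window length in ms (default 7).
#' @param fs sampling rate in Hz.
#' @return smoothed series, same length.
#' @export
smooth_gaussian <- function(series, window = 7, fs = 1000) {
  w <- round(window * fs / 1000)
  if (w < 1) stop("window must span at least one sample")
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  sigma <- w / 5
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(series)
  ok <- !is.na(series)
  v0 <- ifelse(ok, series, 0)
  # zero-padding + running filter implements truncated-window renormalization
  pad <- numeric(half)
  num <- stats::filter(c(pad, v0, pad), k, sides = 2)[(half + 1):(half + n)]
  den <- stats::filter(c(pad, as.numeric(ok), pad), k,
                       sides = 2)[(half + 1):(half + n)]
  out <- as.numeric(num) / as.numeric(den)
  out[!ok] <- NA
  out
}

#' Velocity-threshold saccade detection
#'
#' Detects saccade onsets in one epoch of horizontal gaze as the first
#' samples where the Gaussian-smoothed velocity exceeds five times the
#' median smoothed velocity of the epoch (computed over valid samples),
#' enforcing a 100 ms refractory period between successive onsets.
#' Magnitude and direction come from the difference between the mean gaze
#' position 50-0 ms before and 50-100 ms after the threshold crossing;
#' events with a fully missing pre- or post-window, and zero-displacement
#' events (direction undefined), are dropped.
#'
#' @param x horizontal gaze positions for one epoch (degrees, NA = missing).
#' @param time time axis in ms (same length as `x`).
#' @param threshold_mult velocity threshold as a multiple of the median
#'   (default 5).
#' @param refractory minimum separation of onsets in ms (default 100).
#' @param smooth_window velocity smoothing window in ms (default 7).
#' @param fs sampling rate in Hz.
#' @param min_valid_ms minimum valid data required to attempt detection.
#' @return data.frame with columns `onset` (ms), `magnitude` (degrees),
#'   `direction` ("left"/"right"), `pre_pos`, `post_pos`, `is_micro`
#'   (magnitude < 2 degrees). Zero rows if nothing is detected.
#' @export
detect_saccades <- function(x, time, threshold_mult = 5, refractory = 100,
                            smooth_window = 7, fs = 1000,
                            min_valid_ms = 150) {
  stopifnot(length(x) == length(time))
  empty <- data.frame(onset = numeric(0), magnitude = numeric(0),
                      direction = character(0), pre_pos = numeric(0),
                      post_pos = numeric(0), is_micro = logical(0),
                      stringsAsFactors = FALSE)
  step <- 1000 / fs
  if (sum(!is.na(x)) * step < min_valid_ms) return(empty)
  v <- compute_velocity(x)
  sv <- smooth_gaussian(v, smooth_window, fs)
  med <- stats::median(sv, na.rm = TRUE)
  if (is.na(med)) return(empty)
  thr <- threshold_mult * med
  above <- !is.na(sv) & sv > thr
  if (!any(above)) return(empty)
  onset_idx <- which(above & !c(FALSE, above[-length(above)]))
  # refractory on onsets, first crossing wins
  kept <- onset_idx[1]
  for (i in onset_idx[-1]) {
    if ((time[i] - time[kept[length(kept)]]) >= refractory) kept <- c(kept, i)
  }
  pre_n <- round(50 / step); post_lo <- round(50 / step)
  post_hi <- round(100 / step)
  res <- lapply(kept, function(i) {
    pre_idx <- max(1, i - pre_n):(i - 1)
    post_idx <- (i + post_lo):min(length(x), i + post_hi - 1)
    if (i - 1 < 1 || i + post_lo > length(x)) return(NULL)
    pre <- mean(x[pre_idx], na.rm = TRUE)
    post <- mean(x[post_idx], na.rm = TRUE)
    if (is.nan(pre) || is.nan(post)) return(NULL)
    d <- post - pre
    if (d == 0) return(NULL)      # direction undefined
    data.frame(onset = time[i], magnitude = abs(d),
               direction = if (d > 0) "right" else "left",
               pre_pos = pre, post_pos = post,
               is_micro = abs(d) < 2, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

#' Detect saccades across all epochs of an epoch set
#'
#' @param epochs an `epoch_set` from [epoch_gaze()].
#' @param ... passed to [detect_saccades()].
#' @return data.frame of events with a `trial` column (row index into the
#'   epoch set).
#' @export
detect_saccades_epochs <- function(epochs, ...) {
  out <- vector("list", nrow(epochs$x))
  for (i in seq_len(nrow(epochs$x))) {
    ev <- detect_saccades(epochs$x[i, ], epochs$time, ...)
    if (nrow(ev)) {
      ev$trial <- i
      out[[i]] <- ev
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(onset = numeric(0), magnitude = numeric(0),
                      direction = character(0), pre_pos = numeric(0),
                      post_pos = numeric(0), is_micro = logical(0),
                      trial = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Label saccades as toward or away
#'
#' A saccade is `toward` when its direction matches the memorized side of
#' the reference item on its trial (the cued item for cue-locked analyses,
#' the tested item for test-locked analyses), `away` otherwise.
#'
#' @param events saccade events with `trial` and `direction` columns.
#' @param meta trial metadata with `cue_side` / `tested_side`.
#' @param reference `"cued"` or `"tested"`.
#' @return events with a `label` column ("toward"/"away").
#' @export
label_direction <- function(events, meta, reference = c("cued", "tested")) {
  reference <- match.arg(reference)
  side <- if (reference == "cued") meta$cue_side else meta$tested_side
  if (any(is.na(side))) stop("reference side undefined for some trials")
  if (!nrow(events)) {
    events$label <- character(0)
    return(events)
  }
  ref <- side[events$trial]
  events$label <- ifelse(events$direction == ref, "toward", "away")
  events
}

#' Toward/away saccade-rate time courses
#'
#' Sliding-window rates in Hz: at each time point the number of saccade
#' onsets within a centered `window` ms interval, across trials, divided by
#' `n_trials` times the (possibly edge-truncated) window length in seconds.
#' The bias is defined as toward minus away rate, exactly.
#'
#' @param events labelled events (columns `onset`, `label`).
#' @param n_trials number of trials the events came from (> 0).
#' @param time output time axis in ms.
#' @param window sliding window length in ms (default 50).
#' @return object of class `rate_timecourse`: data.frame(time, toward,
#'   away, bias).
#' @export
rate_timecourse <- function(events, n_trials, time, window = 50) {
  if (n_trials <= 0) stop("n_trials must be positive")
  if (window <= 0) stop("window must be positive")
  t0 <- min(time); t1 <- max(time)
  lo <- pmax(time - window / 2, t0)
  hi <- pmin(time + window / 2, t1)
  len_s <- (hi - lo) / 1000
  count_in <- function(onsets) {
    if (!length(onsets)) return(numeric(length(time)))
    s <- sort(onsets)
    # count in [lo, hi)
    findInterval(hi, s, left.open = TRUE) - findInterval(lo, s, left.open = TRUE)
  }
  toward <- count_in(events$onset[events$label == "toward"]) /
    (n_trials * len_s)
  away <- count_in(events$onset[events$label == "away"]) /
    (n_trials * len_s)
  out <- data.frame(time = time, toward = toward, away = away,
                    bias = toward - away)
  class(out) <- c("rate_timecourse", "data.frame")
  out
}

#' Size-resolved saccade bias map
#'
#' Splits the bias time course by saccade magnitude bins. Events falling
#' outside all bins are collected in an overflow bin (last row) and their
#' count is reported via the `overflow_n` attribute, so that summing over
#' all bins always reproduces the overall bias curve.
#'
#' @param events labelled events with `magnitude`.
#' @param n_trials trial count.
#' @param time time axis in ms.
#' @param size_bins increasing bin edges in degrees.
#' @param window sliding window in ms.
#' @return list of class `size_time_map`: `bias` (bins x time matrix,
#'   rownames = bin labels), `time`, `edges`.
#' @export
size_time_map <- function(events, n_trials, time,
                          size_bins = seq(0, 3, by = 0.5), window = 50) {
  if (is.unsorted(size_bins, strictly = TRUE)) {
    stop("size_bins must be strictly increasing")
  }
  nb <- length(size_bins) - 1
  labels <- paste0("[", size_bins[-length(size_bins)], ",",
                   size_bins[-1], ")")
  bin <- findInterval(events$magnitude, size_bins, left.open = FALSE,
                      rightmost.closed = FALSE)
  bin[bin < 1 | bin > nb] <- nb + 1       # overflow
  overflow_n <- sum(bin == nb + 1)
  m <- matrix(0, nb + 1, length(time),
              dimnames = list(c(labels, "overflow"), NULL))
  for (b in seq_len(nb + 1)) {
    sub <- events[bin == b, , drop = FALSE]
    m[b, ] <- rate_timecourse(sub, n_trials, time, window)$bias
  }
  structure(list(bias = m, time = time, edges = size_bins,
                 overflow_n = overflow_n),
            class = "size_time_map")
}

#' Classify trials by a first toward saccade after the cue
#'
#' A trial is a "toward-saccade" trial when at least one saccade onset
#' falls in the post-cue window (200-600 ms by default) and the first such
#' saccade is labelled toward (reference = cued item).
#'
#' @param events cue-locked labelled events (columns `trial`, `onset`,
#'   `label`).
#' @param n_trials number of trials.
#' @param window classification window in ms post cue.
#' @return logical vector of length `n_trials`.
#' @export
classify_toward_trials <- function(events, n_trials, window = c(200, 600)) {
  out <- rep(FALSE, n_trials)
  if (!nrow(events)) return(out)
  inw <- events$onset >= window[1] & events$onset <= window[2]
  ev <- events[inw, , drop = FALSE]
  if (!nrow(ev)) return(out)
  ev <- ev[order(ev$trial, ev$onset), ]
  first <- ev[!duplicated(ev$trial), ]
  out[first$trial[first$label == "toward"]] <- TRUE
  out
}
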