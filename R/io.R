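#' Write a gaze recording as ASC-like text
#'
#' EyeLink-ASC-style plain text: `MSG <t> <label>` lines for event markers
#' and `<t> <x> <y> <pupil>` sample lines (tab-separated).
#'
#' @param rec a [gaze_recording()].
#' @param path output file.
#' @param events optional data.frame(type, trial, onset) of markers.
#' @export
write_gaze_asc <- function(rec, path, events = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(events)) {
    msg <- sprintf("MSG\t%d %s_trial_%d", as.integer(events$onset),
                   events$type, events$trial)
  } else msg <- character(0)
  pupil <- if (is.null(rec$pupil)) rep(0, length(rec$t)) else rec$pupil
  y <- if (is.null(rec$y)) rep(0, length(rec$t)) else rec$y
  samp <- sprintf("%d\t%.4f\t%.4f\t%.1f", as.integer(rec$t), rec$x, y, pupil)
  # interleave: all messages first is valid ASC practice for epoching
  writeLines(c(msg, samp), con)
  invisible(path)
}

#' Read an ASC-like gaze file
#'
#' @param path file written by [write_gaze_asc()] (or the documented ASC
#'   sample subset: tab-separated `t x y pupil` lines, `MSG` marker lines).
#' @param fs sampling rate in Hz.
#' @return list(rec = [gaze_recording()], events = data.frame(type, trial,
#'   onset)).
#' @export
read_gaze_asc <- function(path, fs = 1000) {
  lines <- readLines(path)
  is_msg <- startsWith(lines, "MSG")
  events <- NULL
  if (any(is_msg)) {
    parts <- strsplit(sub("^MSG\t", "", lines[is_msg]), " ")
    onset <- as.numeric(vapply(parts, `[[`, character(1), 1))
    lab <- vapply(parts, `[[`, character(1), 2)
    events <- data.frame(
      type = sub("_trial_.*$", "", lab),
      trial = as.integer(sub("^.*_trial_", "", lab)),
      onset = onset, stringsAsFactors = FALSE)
  }
  sm <- utils::read.table(text = lines[!is_msg], sep = "\t",
                          col.names = c("t", "x", "y", "pupil"))
  rec <- gaze_recording(t = sm$t, x = sm$x, y = sm$y, pupil = sm$pupil,
                        fs = fs)
  list(rec = rec, events = events)
}

#' Write / read a gaze recording as columnar CSV
#'
#' Columns t, x, y, pupil; NA-safe round trip.
#' @param rec a [gaze_recording()].
#' @param path CSV path.
#' @export
write_gaze_csv <- function(rec, path) {
  df <- data.frame(t = rec$t, x = rec$x,
                   y = if (is.null(rec$y)) NA_real_ else rec$y,
                   pupil = if (is.null(rec$pupil)) NA_real_ else rec$pupil)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @param fs sampling rate in Hz.
#' @export
read_gaze_csv <- function(path, fs = 1000) {
  df <- utils::read.csv(path)
  gaze_recording(t = df$t, x = df$x,
                 y = if (all(is.na(df$y))) NULL else df$y,
                 pupil = if (all(is.na(df$pupil))) NULL else df$pupil,
                 fs = fs)
}

#' Write / read EEG epochs as plain-text container
#'
#' Serializes an `eeg_epoch_set` as a wide CSV (one row per channel x
#' trial, samples as columns) plus a JSON sidecar carrying channel names,
#' sampling rate, time axis, lock and trial metadata.
#'
#' @param epochs an `eeg_epoch_set`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_eeg_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(channels = epochs$channels, fs = epochs$fs,
               time = epochs$time, lock = epochs$lock,
               n_trials = d[2], meta = epochs$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = ","))
  n_ch <- length(side$channels)
  n_tr <- side$n_trials
  dat <- aperm(array(flat, dim = c(n_tr, n_ch, ncol(flat))), c(2, 1, 3))
  dimnames(dat) <- list(side$channels, NULL, NULL)
  structure(list(data = dat, fs = side$fs, channels = side$channels,
                 time = side$time, lock = side$lock,
                 meta = as.data.frame(side$meta)),
            class = "eeg_epoch_set")
}
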