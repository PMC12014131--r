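#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed with stage labels (stage name, subject, block) so
#' each stochastic stage of a simulated study gets its own reproducible
#' stream. Result is always a positive 32-bit integer.
#' @keywords internal
derive_seed <- function(master, ...) {
  key <- paste(c(...), collapse = ":")
  v <- utf8ToInt(key)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(master) * 69069 + h * 9973) %% 2147483629 + 1)
}

#' Raised-cosine-edged bump profile
#'
#' Weight in [0, 1] as a function of time since the locking event: zero
#' before `onset`, cosine rise over `rise` ms, flat plateau over `plateau`
#' ms, cosine fall over `fall` ms, zero after. The flat plateau makes a
#' plateau extension map one-to-one onto the 50%-of-peak offset latency.
#'
#' @param t numeric vector, ms relative to the locking event.
#' @param onset,rise,plateau,fall segment durations in ms.
#' @return numeric vector of weights in [0, 1].
#' @export
bias_profile <- function(t, onset, rise, plateau, fall) {
  u <- t - onset
  w <- numeric(length(t))
  idx <- u >= 0 & u < rise
  w[idx] <- 0.5 * (1 - cos(pi * u[idx] / rise))
  idx <- u >= rise & u < rise + plateau
  w[idx] <- 1
  idx <- u >= rise + plateau & u < rise + plateau + fall
  w[idx] <- 0.5 * (1 + cos(pi * (u[idx] - rise - plateau) / fall))
  w
}

#' Simulate a microsaccade event train
#'
#' Inhomogeneous Poisson point process by thinning, with a 100 ms refractory
#' period between successive events. Each event gets a direction (+1 with
#' probability `toward_prob_fn(t)`, else -1) and an amplitude drawn from a
#' truncated lognormal main-sequence range (mostly below 2 degrees).
#'
#' @param rate_fn function of time (ms) returning the event rate in Hz (>= 0).
#' @param toward_prob_fn function of time (ms) returning the probability in
#'   [0, 1] that an event at that time goes in the positive direction.
#' @param duration train duration in ms (>= 0).
#' @param main_sequence list with `amp_meanlog`, `amp_sdlog`, `amp_range`.
#' @param refractory minimum separation between events, ms.
#' @return data.frame with columns `time` (ms), `direction` (+1/-1),
#'   `amplitude` (degrees); zero rows if no events.
#' @export
simulate_microsaccade_train <- function(rate_fn, toward_prob_fn, duration,
                                        main_sequence = list(
                                          amp_meanlog = log(0.5),
                                          amp_sdlog = 0.6,
                                          amp_range = c(0.1, 3)),
                                        refractory = 100) {
  if (duration < 0) stop("duration must be non-negative")
  empty <- data.frame(time = numeric(0), direction = numeric(0),
                      amplitude = numeric(0))
  if (duration == 0) return(empty)
  grid <- seq(0, duration, by = 1)
  rates <- rate_fn(grid)
  if (any(rates < 0)) stop("rate_fn must be non-negative")
  lambda_max <- max(rates)
  if (lambda_max <= 0) return(empty)
  n_cand <- stats::rpois(1, lambda_max * duration / 1000)
  if (n_cand == 0) return(empty)
  cand <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < rate_fn(cand) / lambda_max
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  # refractory: greedy first-event-wins
  acc <- cand[1]
  if (length(cand) > 1) {
    for (tt in cand[-1]) if (tt - acc[length(acc)] >= refractory) acc <- c(acc, tt)
  }
  p <- toward_prob_fn(acc)
  if (any(p < 0 | p > 1)) stop("toward_prob_fn must return values in [0, 1]")
  dir <- ifelse(stats::runif(length(acc)) < p, 1, -1)
  amp <- .draw_amplitudes(length(acc), main_sequence)
  data.frame(time = acc, direction = dir, amplitude = amp)
}

.draw_amplitudes <- function(n, ms) {
  lo <- ms$amp_range[1]; hi <- ms$amp_range[2]
  a <- stats::rlnorm(n, ms$amp_meanlog, ms$amp_sdlog)
  bad <- a < lo | a > hi
  while (any(bad)) {
    a[bad] <- stats::rlnorm(sum(bad), ms$amp_meanlog, ms$amp_sdlog)
    bad <- a < lo | a > hi
  }
  a
}

#' Trial metadata for one simulated block
#'
#' Validity assignment is deterministic in count (e.g. exactly 200 valid and
#' 50 invalid trials in an 80% block of 250) with shuffled trial order.
#' @keywords internal
.block_meta <- function(cfg, subject, reliability, block_index) {
  n <- cfg$trials_per_block
  frac <- .validity_fraction_for[[reliability]]
  n_valid <- round(frac * n)
  valid <- sample(rep(c(TRUE, FALSE), c(n_valid, n - n_valid)))
  cue_side <- sample(c("left", "right"), n, replace = TRUE)
  tested_side <- ifelse(valid, cue_side,
                        ifelse(cue_side == "left", "right", "left"))
  lay <- cfg$layout
  t0 <- (block_index - 1) * n * lay$trial_len
  trial_start <- t0 + (seq_len(n) - 1) * lay$trial_len
  data.frame(subject = subject,
             block = reliability,
             trial = seq_len(n),
             cue_side = cue_side,
             valid = valid,
             tested_side = tested_side,
             true_orientation = stats::runif(n, 0, 180),
             trial_start = trial_start,
             cue_onset = trial_start + lay$cue_onset,
             test_onset = trial_start + lay$test_onset,
             stringsAsFactors = FALSE)
}

#' Probability that a saccade at time t (ms within trial) goes rightward
#' @keywords internal
.p_right_trial <- function(t_in_trial, meta_row, cfg) {
  lay <- cfg$layout
  cb <- cfg$cue_bias; tb <- cfg$test_bias
  g_cue <- cb$gain[[meta_row$block]]
  s_cue <- if (meta_row$cue_side == "right") 1 else -1
  s_test <- if (meta_row$tested_side == "right") 1 else -1
  plateau_t <- tb$plateau + if (!meta_row$valid) tb$invalid_offset_extension else 0
  w_cue <- bias_profile(t_in_trial - lay$cue_onset,
                        cb$onset, cb$rise, cb$plateau, cb$fall)
  w_test <- bias_profile(t_in_trial - lay$test_onset,
                         tb$onset, tb$rise, plateau_t, tb$fall)
  p <- 0.5 + g_cue * w_cue * s_cue + tb$gain * w_test * s_test
  pmin(pmax(p, 0.02), 0.98)
}

#' Simulate one subject's full session
#'
#' Generates, for every configured reliability block: trial metadata with
#' deterministic validity counts, a continuous 1000 Hz gaze recording
#' (fixational drift + injected saccade waveforms + blink zero-runs) with
#' cue/test event markers, and the behavioral report table. The injected
#' ground-truth saccade events are returned for injection-recovery
#' validation. EEG epochs are generated on demand via
#' [simulate_eeg_epochs()] to keep session objects light.
#'
#' @param cfg a [sim_config()] object.
#' @param subject subject identifier (integer).
#' @return list with elements `gaze` (a `gaze_recording`), `events`
#'   (data.frame of cue/test markers: type, row index into `meta`, onset ms),
#'   `meta` (trial metadata), `behavior` (behavior table), and `truth`
#'   (injected saccade events with absolute and within-trial times).
#' @export
simulate_session <- function(cfg, subject = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "session", subject))
  lay <- cfg$layout
  metas <- list(); truths <- list(); xs <- list(); ys <- list()
  for (bi in seq_along(cfg$reliabilities)) {
    rel <- cfg$reliabilities[bi]
    meta <- .block_meta(cfg, subject, rel, bi)
    n_samp <- cfg$trials_per_block * lay$trial_len
    # injected saccade events per trial
    ev_list <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      row <- meta[i, ]
      ev <- simulate_microsaccade_train(
        rate_fn = function(t) rep(cfg$base_saccade_rate, length(t)),
        toward_prob_fn = function(t) .p_right_trial(t, row, cfg),
        duration = lay$trial_len - 1,
        main_sequence = cfg$main_sequence)
      if (nrow(ev)) {
        ev$trial <- i
        ev$time_abs <- meta$trial_start[i] + ev$time
      }
      ev_list[[i]] <- ev
    }
    keep <- vapply(ev_list, nrow, integer(1)) > 0
    ev <- if (any(keep)) do.call(rbind, ev_list[keep]) else NULL
    if (is.null(ev)) {
      ev <- data.frame(time = numeric(0), direction = numeric(0),
                       amplitude = numeric(0), trial = integer(0),
                       time_abs = numeric(0))
    }
    ev$block <- rep(rel, nrow(ev))
    tr <- .gaze_trace(n_samp, ev, cfg,
                      t_offset = (bi - 1) * n_samp, meta = meta)
    metas[[bi]] <- meta; truths[[bi]] <- ev
    xs[[bi]] <- tr$x; ys[[bi]] <- tr$y
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  truth <- do.call(rbind, truths)
  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  rec <- gaze_recording(t = seq_along(x) - 1, x = x, y = y, fs = cfg$fs)
  events <- rbind(
    data.frame(type = "cue", trial = seq_len(nrow(meta)),
               onset = meta$cue_onset),
    data.frame(type = "test", trial = seq_len(nrow(meta)),
               onset = meta$test_onset))
  behavior <- simulate_behavior(meta, cfg$behavior)
  list(gaze = rec, events = events, meta = meta,
       behavior = behavior, truth = truth, config = cfg, subject = subject)
}

#' Drift + saccade + blink gaze trace for one block
#' @keywords internal
.gaze_trace <- function(n_samp, ev, cfg, t_offset, meta) {
  d <- cfg$drift
  a <- exp(-1 / d$vel_tau)
  sd_v <- d$speed_sd / 1000            # deg/ms per axis
  innov_sd <- sd_v * sqrt(1 - a^2)
  drift_axis <- function() {
    v <- stats::filter(stats::rnorm(n_samp, 0, innov_sd), a,
                       method = "recursive")
    as.numeric(stats::filter(as.numeric(v), 1 - 1 / d$pos_tau,
                             method = "recursive"))
  }
  x <- drift_axis(); y <- drift_axis()
  # saccade waveform: sigmoid displacement, injected as velocity increments,
  # with slow recentring so gaze stays near fixation
  if (nrow(ev)) {
    tau <- cfg$main_sequence$vpeak_slope
    span <- 20
    u <- seq(-span, span)
    shape <- stats::plogis((u + 0.5) / tau) - stats::plogis((u - 0.5) / tau)
    vinc <- numeric(n_samp)
    # event time marks saccade ONSET; the sigmoid displacement is centered
    # 10 ms later so motion starts at the event time
    center <- round(ev$time_abs - t_offset) + 1 + 10
    for (k in seq_len(nrow(ev))) {
      idx <- center[k] + u
      ok <- idx >= 1 & idx <= n_samp
      vinc[idx[ok]] <- vinc[idx[ok]] +
        ev$amplitude[k] * ev$direction[k] * shape[ok]
    }
    x <- x + as.numeric(stats::filter(vinc, 1 - 1 / 800, method = "recursive"))
  }
  # blinks: zero-runs, Poisson in time
  bl <- cfg$blink
  n_blink <- stats::rpois(1, bl$rate * n_samp / 1000)
  if (n_blink > 0) {
    starts <- stats::runif(n_blink, 0, n_samp - bl$duration)
    if (cfg$clean_blinks) {
      # keep padded blink clear of the 0-900 ms post-test window
      for (k in seq_len(n_blink)) {
        tries <- 0
        while (.blink_hits_test(starts[k], bl$duration, meta, t_offset) &&
               tries < 200) {
          starts[k] <- stats::runif(1, 0, n_samp - bl$duration)
          tries <- tries + 1
        }
      }
    }
    for (s in starts) {
      idx <- seq(floor(s) + 1, min(floor(s) + bl$duration, n_samp))
      x[idx] <- 0; y[idx] <- 0
    }
  }
  list(x = x, y = y)
}

.blink_hits_test <- function(start, duration, meta, t_offset) {
  lo <- start + t_offset - 100          # padded blink extent, absolute ms
  hi <- start + t_offset + duration + 100
  any(hi >= meta$test_onset & lo <= meta$test_onset + 900)
}

#' Simulate EEG epochs for a set of trials
#'
#' Per trial and channel: a 10 Hz (configurable) oscillation with random
#' phase plus AR(1) background noise. From `alpha$onset` ms after the
#' locking event, lateral-channel amplitudes are scaled so the true
#' signal-power lateralization (contralateral vs ipsilateral to the
#' reference side) equals the configured percentage for that block's
#' reliability; midline channels stay at base amplitude.
#'
#' @param cfg a [sim_config()].
#' @param meta trial metadata (rows define the epochs).
#' @param lock `"cue"` or `"test"`; sets the epoch window ([-200, 1500] or
#'   [-200, 900] ms) and the reference side (cued vs tested item).
#' @param channels channel labels; defaults to [default_montage()].
#' @param subject used only for seed derivation.
#' @return an `eeg_epoch_set`: list(data = channels x trials x time array,
#'   fs, channels, time, lock, meta).
#' @export
simulate_eeg_epochs <- function(cfg, meta, lock = c("cue", "test"),
                                channels = default_montage(), subject = 1L) {
  lock <- match.arg(lock)
  set.seed(derive_seed(cfg$seed, "eeg", subject, lock))
  win <- epoch_window(lock)
  fs <- cfg$fs_eeg
  time <- seq(win[1], win[2], by = 1000 / fs)
  nt <- length(time)
  n_trial <- nrow(meta)
  al <- cfg$alpha
  hemi <- channel_hemisphere(channels)
  ref_side <- if (lock == "cue") meta$cue_side else meta$tested_side
  omega <- 2 * pi * al$freq / 1000
  post <- time >= al$onset
  n_ch <- length(channels)
  K <- n_ch * n_trial                  # columns: channel fastest, then trial
  # contralateral amp^2 scaled by (1 + L/100), ipsilateral by (1 - L/100)
  L <- al$lateralization_pct[meta$block]            # per trial
  contra_hemi <- ifelse(ref_side == "left", "right", "left")
  scale2 <- matrix(1, n_ch, n_trial)
  for (i in seq_len(n_trial)) {
    scale2[, i] <- ifelse(hemi == "mid", 1,
                          ifelse(hemi == contra_hemi[i],
                                 1 + L[i] / 100, 1 - L[i] / 100))
  }
  post_amp <- al$base_amp * sqrt(as.vector(scale2))  # length K
  amp <- matrix(al$base_amp, nt, K)
  amp[post, ] <- rep(post_amp, each = sum(post))
  phase <- stats::runif(K, 0, 2 * pi)
  sig <- amp * sin(outer(omega * time, phase, "+"))
  noise <- stats::filter(matrix(stats::rnorm(nt * K, 0, al$noise_sd), nt, K),
                         al$noise_ar, method = "recursive")
  M <- sig + matrix(as.numeric(noise), nt, K)
  dat <- aperm(array(M, dim = c(nt, n_ch, n_trial)), c(2, 3, 1))
  dimnames(dat) <- list(channels, NULL, NULL)
  structure(list(data = dat, fs = fs, channels = channels, time = time,
                 lock = lock, meta = meta),
            class = "eeg_epoch_set")
}

#' Simulate one EEG trial
#'
#' Convenience wrapper around [simulate_eeg_epochs()] for a single trial.
#' @inheritParams simulate_eeg_epochs
#' @param meta_row single-row trial metadata.
#' @return channels x time matrix.
#' @export
simulate_eeg_trial <- function(cfg, meta_row, lock = "cue",
                               channels = default_montage(), subject = 1L) {
  ep <- simulate_eeg_epochs(cfg, meta_row, lock, channels, subject)
  out <- ep$data[, 1, ]
  rownames(out) <- channels
  out
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; angles in (-pi, pi].
#' @param n number of draws.
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return numeric vector of angles (radians).
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Simulate behavioral reports
#'
#' Reported orientation = true orientation plus von Mises noise on the
#' doubled 180-degree orientation circle (concentration depends on cue
#' validity); RT is lognormal with a validity-dependent location parameter
#' (invalid slower).
#'
#' @param meta trial metadata.
#' @param params behavior parameter list (see [sim_config()]).
#' @return `meta` augmented with `rt` (s), `reported` (degrees in (0, 180]),
#'   `error` (degrees in [0, 90]) and `score` (0-100).
#' @export
simulate_behavior <- function(meta, params) {
  n <- nrow(meta)
  kappa <- ifelse(meta$valid, params$kappa_valid, params$kappa_invalid)
  theta <- numeric(n)
  for (k in unique(kappa)) {
    idx <- which(kappa == k)
    theta[idx] <- rvonmises(length(idx), k)
  }
  err_deg <- theta * 90 / pi                    # (-90, 90] on orientation space
  reported <- (meta$true_orientation + err_deg) %% 180
  reported[reported == 0] <- 180
  meanlog <- ifelse(meta$valid, params$rt_meanlog_valid,
                    params$rt_meanlog_invalid)
  rt <- stats::rlnorm(n, meanlog, params$rt_sdlog)
  out <- meta
  out$rt <- rt
  out$reported <- reported
  out$error <- reproduction_error(reported, meta$true_orientation)
  out$score <- feedback_score(out$error)
  out
}

#' Mirror a simulated session
#'
#' Flips all cue/tested sides, negates the horizontal gaze channel, and
#' flips injected saccade directions. With the analyses being left/right
#' symmetric, every toward/away labelled quantity computed from the mirrored
#' session equals that of the original exactly.
#'
#' @param session result of [simulate_session()].
#' @return mirrored session (without EEG; regenerate if needed).
#' @export
mirror_session <- function(session) {
  flip <- function(s) ifelse(s == "left", "right", "left")
  session$meta$cue_side <- flip(session$meta$cue_side)
  session$meta$tested_side <- flip(session$meta$tested_side)
  session$gaze$x <- -session$gaze$x
  if (nrow(session$truth)) session$truth$direction <- -session$truth$direction
  if (!is.null(session$behavior)) {
    session$behavior$cue_side <- flip(session$behavior$cue_side)
    session$behavior$tested_side <- flip(session$behavior$tested_side)
  }
  session
}
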