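make_epochs <- function(signal_fn, n_trials = 4, fs = 200,
                        channels = c("P3", "P4"), window = c(-200, 900)) {
  time <- seq(window[1], window[2], by = 1000 / fs)
  dat <- array(0, dim = c(length(channels), n_trials, length(time)),
               dimnames = list(channels, NULL, NULL))
  for (c in seq_along(channels)) {
    for (i in seq_len(n_trials)) dat[c, i, ] <- signal_fn(time, c, i)
  }
  structure(list(data = dat, fs = fs, channels = channels, time = time,
                 lock = "cue", meta = NULL), class = "eeg_epoch_set")
}

test_that("a pure 10 Hz sinusoid peaks at 10 Hz at all interior times", {
  ep <- make_epochs(function(t, c, i) sin(2 * pi * 10 * t / 1000))
  tfr <- stft_power(ep)
  peak_freq <- apply(tfr$power[1, , ], 2, function(p) tfr$freqs[which.max(p)])
  expect_true(all(peak_freq == 10))
  # power scaling: amplitude a -> a^2/2 at the target bin
  expect_equal(max(tfr$power[1, , 5]), 0.5, tolerance = 0.01)
})

test_that("zero signal gives zero power; doubling amplitude quadruples power", {
  ep0 <- make_epochs(function(t, c, i) 0)
  expect_true(all(stft_power(ep0)$power == 0))
  ep1 <- make_epochs(function(t, c, i) sin(2 * pi * 10 * t / 1000))
  ep2 <- make_epochs(function(t, c, i) 2 * sin(2 * pi * 10 * t / 1000))
  p1 <- stft_power(ep1, freqs = 10)$power
  p2 <- stft_power(ep2, freqs = 10)$power
  expect_equal(p2, 4 * p1, tolerance = 1e-9)
})

test_that("windows never extend beyond the epoch", {
  ep <- make_epochs(function(t, c, i) rnorm(length(t)))
  tfr <- stft_power(ep)
  expect_gte(min(tfr$times), min(ep$time) + 150 - 5)
  expect_lte(max(tfr$times), max(ep$time) - 150 + 5)
  expect_error(stft_power(ep, freqs = 2:150), "too low")
})

test_that("alpha band power is the 8-12 Hz mean", {
  ep <- make_epochs(function(t, c, i) rnorm(length(t)))
  tfr <- stft_power(ep)
  tfr$power[1, , ] <- matrix(rep(as.numeric(tfr$freqs), ncol(tfr$power[1, , ])),
                             nrow = length(tfr$freqs))  # linear in frequency
  a <- alpha_power(tfr)
  expect_equal(unname(a[1, ]), rep(10, ncol(a)))  # band mean = value at 10 Hz
  # flat spectrum c -> c
  tfr$power[2, , ] <- 3.7
  expect_equal(unname(alpha_power(tfr)[2, ]), rep(3.7, ncol(a)))
})

test_that("lateralization index follows the contrast formula and antisymmetry", {
  chans <- c("P3", "P4")
  times <- 1:5
  mk <- function(v) {
    m <- matrix(v, 2, 5, byrow = TRUE)
    rownames(m) <- chans
    attr(m, "times") <- times
    m
  }
  cl <- list(left = "P3", right = "P4")
  # attend-left power 1 everywhere, attend-right power 3 everywhere:
  # left cluster: contra (right trials) 3, ipsi 1 -> +50
  # right cluster: contra (left trials) 1, ipsi 3 -> -50; average 0
  tc <- lateralization_timecourse(mk(1), mk(3), cl)
  expect_equal(tc$index, rep(0, 5))
  # channel-specific: P3 = 3 on attend-right, 1 otherwise; P4 = 1 always
  al <- mk(1)
  ar <- mk(1)
  ar["P3", ] <- 3
  tc2 <- lateralization_timecourse(al, ar, cl)
  expect_equal(tc2$index, rep(25, 5))  # left cluster +50, right cluster 0
  # swapping the trial groups negates the cluster contrasts
  tc3 <- lateralization_timecourse(ar, al, cl)
  expect_equal(tc3$index, -tc2$index)
  # equal power -> 0
  expect_equal(lateralization_timecourse(mk(2), mk(2), cl)$index, rep(0, 5))
  # bounded in [-100, 100] for positive power
  expect_true(all(abs(tc2$index) <= 100))
  # missing channels and non-positive power raise errors
  expect_error(lateralization_timecourse(mk(1), mk(1),
                                         list(left = "O1", right = "P4")),
               "not present")
  expect_error(lateralization_timecourse(mk(0), mk(0), cl), "non-positive")
})

test_that("topography: identical conditions give zeros; scaling leaves map unchanged", {
  chans <- c("P3", "P4", "Pz")
  mk <- function(v) {
    m <- matrix(v, 3, 10)
    rownames(m) <- chans
    attr(m, "times") <- seq(0, 900, by = 100)
    m
  }
  expect_equal(unname(lateralization_topography(mk(2), mk(2))), rep(0, 3))
  al <- mk(2)
  ar <- mk(3)
  expect_equal(lateralization_topography(al, ar),
               lateralization_topography(10 * al, 10 * ar))
})

test_that("simulated lateralization shows sign-symmetric posterior topography", {
  cfg <- sim_config(trials_per_block = 120, reliabilities = "80", seed = 88)
  meta <- subset(simulate_session(cfg, 1)$meta, block == "80")
  ep <- simulate_eeg_epochs(cfg, meta, "cue", subject = 1)
  tl <- which(meta$cue_side == "left")
  tr <- which(meta$cue_side == "right")
  al <- alpha_power(stft_power(ep, freqs = 8:12, trials = tl))
  ar <- alpha_power(stft_power(ep, freqs = 8:12, trials = tr))
  topo <- lateralization_topography(al, ar, c(400, 800))
  # with the negative configured modulation, attending left reduces
  # right-hemisphere (contralateral) power, so the attend-left-vs-right
  # contrast is negative over the right hemisphere and positive on the left
  expect_true(all(topo[c("P4", "PO8", "O2")] < 0))
  expect_true(all(topo[c("P3", "PO7", "O1")] > 0))
  # sign-symmetric up to sampling noise: the residual asymmetry is small
  # relative to the hemispheric difference itself
  expect_lt(abs(topo[["P3"]] + topo[["P4"]]),
            0.3 * abs(topo[["P3"]] - topo[["P4"]]))
  expect_lt(abs(topo[["Pz"]]), 1)                 # midline unmodulated
})

test_that("window averaging: constant, symmetric, and ramp cases", {
  tc <- data.frame(time = seq(400, 800, by = 10), index = 4.2)
  expect_equal(window_average(tc), 4.2)
  tc$index <- seq(-5, 5, length.out = nrow(tc))
  expect_equal(window_average(tc), 0)
  tc$index <- seq(0, 10, length.out = nrow(tc))
  expect_equal(window_average(tc), 5)  # linear ramp -> midpoint
  expect_error(window_average(tc, c(2000, 3000)), "outside")
})
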