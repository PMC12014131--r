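test_that("velocity is the absolute consecutive distance with NA propagation", {
  expect_equal(compute_velocity(rep(2, 10)), rep(0, 10))
  expect_equal(compute_velocity(c(0, 0, 1.5, 1.5)), c(0, 0, 1.5, 0))
  v <- compute_velocity(c(0, 0, NA, 1.5, 1.5))
  expect_true(is.na(v[3]) && is.na(v[4]))
  expect_equal(v[5], 0)
  expect_error(compute_velocity(1), "length")
})

test_that("Gaussian smoothing: constant invariance, kernel impulse response", {
  expect_equal(smooth_gaussian(rep(3.2, 100)), rep(3.2, 100))
  imp <- c(rep(0, 50), 1, rep(0, 50))
  sm <- smooth_gaussian(imp)
  # response equals the normalized 7-sample Gaussian kernel, sigma = 7/5
  k <- dnorm(-3:3, sd = 7 / 5)
  k <- k / sum(k)
  expect_equal(sm[48:54], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm[48:54], rev(sm[48:54]))  # symmetry
  expect_error(smooth_gaussian(1:10, window = 0.2), "at least one sample")
})

test_that("smoothing preserves the mean of long constant-padded signals", {
  set.seed(1)
  x <- c(rep(0, 200), rnorm(500), rep(0, 200))
  expect_equal(mean(smooth_gaussian(x)), mean(x), tolerance = 1e-10)
})

test_that("a noise-free step is detected once with correct size and side", {
  se <- step_epoch(500, 1.5)
  ev <- detect_saccades(se$x, se$time)
  expect_equal(nrow(ev), 1)
  # centered 7 ms kernel spreads the velocity impulse by up to 3 samples
  expect_lte(abs(ev$onset - 500), 3)
  expect_equal(ev$magnitude, 1.5, tolerance = 1e-9)
  expect_equal(ev$direction, "right")
  expect_true(ev$is_micro)
})

test_that("a flat epoch produces no events", {
  expect_equal(nrow(detect_saccades(rep(0.3, 1000), 0:999)), 0)
})

test_that("two steps 40 ms apart collapse to one onset (refractory)", {
  se <- step_epoch(400, 1)
  se$x[se$time >= 440] <- se$x[se$time >= 440] + 1
  ev <- detect_saccades(se$x, se$time)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset - 400), 3)
  # 150 ms apart -> two events
  se2 <- step_epoch(400, 1)
  se2$x[se2$time >= 550] <- se2$x[se2$time >= 550] + 1
  expect_equal(nrow(detect_saccades(se2$x, se2$time)), 2)
})

test_that("adding a constant offset changes no detected event", {
  set.seed(12)
  x <- cumsum(rnorm(1500, 0, 0.001))
  x[700:1500] <- x[700:1500] + 0.8
  ev1 <- detect_saccades(x, 0:1499)
  ev2 <- detect_saccades(x + 5.3, 0:1499)
  expect_equal(ev1$onset, ev2$onset)
  expect_equal(ev1$magnitude, ev2$magnitude)
})

test_that("an all-missing epoch yields an empty list", {
  expect_equal(nrow(detect_saccades(rep(NA_real_, 1000), 0:999)), 0)
})

test_that("toward/away labels follow the reference item's side", {
  meta <- data.frame(cue_side = c("left", "right"),
                     tested_side = c("right", "right"))
  ev <- data.frame(trial = c(1, 1, 2), direction = c("left", "right", "left"),
                   stringsAsFactors = FALSE)
  lab_cued <- label_direction(ev, meta, "cued")
  expect_equal(lab_cued$label, c("toward", "away", "away"))
  lab_tested <- label_direction(ev, meta, "tested")
  expect_equal(lab_tested$label, c("away", "toward", "away"))
  # mirroring sides and directions swaps no label
  meta_m <- data.frame(cue_side = c("right", "left"),
                       tested_side = c("left", "left"))
  ev_m <- ev
  ev_m$direction <- c("right", "left", "right")
  expect_equal(label_direction(ev_m, meta_m, "cued")$label, lab_cued$label)
})

test_that("rate time course: point mass, empty input, and duplication invariance", {
  time <- seq(-200, 900)
  ev <- data.frame(trial = 1:100, onset = rep(300, 100),
                   label = rep("toward", 100))
  rc <- rate_timecourse(ev, 100, time)
  expect_equal(rc$toward[rc$time == 300], 20)  # 1 / 0.05 s
  expect_equal(rc$away, rep(0, length(time)))
  expect_equal(rc$bias, rc$toward - rc$away)
  # no events -> zero everywhere
  rc0 <- rate_timecourse(ev[0, ], 100, time)
  expect_true(all(rc0$toward == 0 & rc0$away == 0))
  # duplicating events and trials leaves rates unchanged
  ev2 <- rbind(ev, transform(ev, trial = trial + 100))
  rc2 <- rate_timecourse(ev2, 200, time)
  expect_equal(rc2$toward, rc$toward)
  expect_error(rate_timecourse(ev, 0, time), "positive")
})

test_that("edge windows are truncated with a matching denominator", {
  time <- seq(0, 200)
  ev <- data.frame(trial = 1, onset = 10, label = "toward")
  rc <- rate_timecourse(ev, 1, time)
  # at t = 0 the window is [0, 25): length 25 ms, event at 10 inside
  expect_equal(rc$toward[1], 1 / 0.025)
})

test_that("size-resolved map partitions the overall bias", {
  set.seed(4)
  ev <- data.frame(trial = sample(1:50, 300, TRUE),
                   onset = runif(300, -200, 900),
                   label = sample(c("toward", "away"), 300, TRUE),
                   magnitude = rlnorm(300, log(0.6), 0.8))
  time <- seq(-200, 900, by = 5)
  m <- size_time_map(ev, 50, time, size_bins = seq(0, 2, 0.5))
  overall <- rate_timecourse(ev, 50, time)$bias
  expect_equal(colSums(m$bias), overall, tolerance = 1e-12)
  expect_equal(m$overflow_n, sum(ev$magnitude >= 2))
  # a single large saccade lands only in the overflow bin
  ev3 <- data.frame(trial = 1, onset = 100, label = "toward", magnitude = 3)
  m3 <- size_time_map(ev3, 1, time, size_bins = seq(0, 2, 0.5))
  expect_true(all(m3$bias[rownames(m3$bias) != "overflow", ] == 0))
  expect_gt(max(m3$bias["overflow", ]), 0)
})

test_that("micro-only events reproduce the bias course shape", {
  # restricting to sub-2-degree events recovers the same curve when all
  # events are micro-saccades
  set.seed(9)
  ev <- data.frame(trial = sample(1:30, 200, TRUE),
                   onset = runif(200, 0, 800),
                   label = sample(c("toward", "away"), 200, TRUE,
                                  prob = c(0.7, 0.3)),
                   magnitude = runif(200, 0.2, 1.9))
  time <- seq(0, 800, by = 2)
  full <- rate_timecourse(ev, 30, time)$bias
  micro <- rate_timecourse(ev[ev$magnitude < 2, ], 30, time)$bias
  expect_equal(micro, full)
})

test_that("toward-trial classification follows the first in-window saccade", {
  ev <- data.frame(trial = c(1, 2, 3, 3, 4),
                   onset = c(300, 150, 250, 400, 700),
                   label = c("toward", "toward", "away", "toward", "toward"))
  out <- classify_toward_trials(ev, 5)
  expect_equal(out, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("injected saccades are recovered on drifting traces", {
  cfg <- sim_config(trials_per_block = 60, reliabilities = "80", seed = 33)
  ses <- simulate_session(cfg, 1)
  ep <- epoch_gaze(mask_blinks(ses$gaze), ses$meta$trial_start, "cue",
                   window = c(0, 3999))
  ev <- detect_saccades_epochs(ep)
  tr <- ses$truth[ses$truth$amplitude >= 0.3, ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    cand <- ev$onset[ev$trial == tr$trial[i]]
    length(cand) > 0 && min(abs(cand - tr$time[i])) <= 10
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})
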