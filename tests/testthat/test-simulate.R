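test_that("identical seeds give bit-identical sessions", {
  cfg <- sim_config(trials_per_block = 8, reliabilities = c("100", "80"),
                    seed = 42)
  a <- simulate_session(cfg, 1)
  b <- simulate_session(cfg, 1)
  expect_identical(a$gaze$x, b$gaze$x)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$behavior, b$behavior)
  # different subject -> different stream
  c <- simulate_session(cfg, 2)
  expect_false(identical(a$gaze$x, c$gaze$x))
})

test_that("validity counts are deterministic: 80% of 250 = 200 valid", {
  cfg <- sim_config(trials_per_block = 250, reliabilities = "80", seed = 9)
  ses <- simulate_session(cfg, 1)
  expect_equal(sum(ses$meta$valid), 200)
  expect_equal(sum(!ses$meta$valid), 50)
  expect_true(all(ses$meta$tested_side[ses$meta$valid] ==
                    ses$meta$cue_side[ses$meta$valid]))
  expect_true(all(ses$meta$tested_side[!ses$meta$valid] !=
                    ses$meta$cue_side[!ses$meta$valid]))
})

test_that("100% blocks contain only valid trials", {
  cfg <- sim_config(trials_per_block = 30,
                    reliabilities = c("imp100", "100"), seed = 3)
  ses <- simulate_session(cfg, 1)
  expect_true(all(ses$meta$valid))
})

test_that("invalid reliability labels are rejected", {
  expect_error(sim_config(reliabilities = "95"), "invalid reliability")
})

test_that("microsaccade train: zero rate gives no events, negative duration errors", {
  ev <- simulate_microsaccade_train(function(t) rep(0, length(t)),
                                    function(t) rep(0.5, length(t)), 10000)
  expect_equal(nrow(ev), 0)
  expect_error(simulate_microsaccade_train(function(t) rep(1, length(t)),
                                           function(t) rep(0.5, length(t)),
                                           -5), "non-negative")
})

test_that("homogeneous train without refractory is Poisson-calibrated", {
  set.seed(101)
  n <- replicate(40, nrow(simulate_microsaccade_train(
    function(t) rep(2, length(t)), function(t) rep(0.5, length(t)),
    1e6, refractory = 0)))
  # each replicate: mean 2000, sd sqrt(2000); mean of 40 has se sqrt(2000/40)
  expect_lt(abs(mean(n) - 2000), 3 * sqrt(2000 / 40))
})

test_that("toward probability 0.5 gives symmetric directions", {
  set.seed(7)
  ev <- simulate_microsaccade_train(function(t) rep(2, length(t)),
                                    function(t) rep(0.5, length(t)),
                                    5e5, refractory = 0)
  n <- nrow(ev)
  expect_lt(abs(sum(ev$direction == 1) - n / 2), 3 * sqrt(n) / 2 + 1)
})

test_that("amplitudes respect the main-sequence range and are mostly micro", {
  set.seed(5)
  ev <- simulate_microsaccade_train(function(t) rep(3, length(t)),
                                    function(t) rep(0.5, length(t)), 2e5,
                                    refractory = 0)
  expect_true(all(ev$amplitude >= 0.1 & ev$amplitude <= 3))
  expect_gt(mean(ev$amplitude < 2), 0.9)
})

test_that("refractory period enforces 100 ms minimum separation", {
  set.seed(2)
  ev <- simulate_microsaccade_train(function(t) rep(20, length(t)),
                                    function(t) rep(0.5, length(t)), 1e5)
  expect_true(all(diff(ev$time) >= 100))
})

test_that("cue-bias gains produce reliability-ordered toward-probability elevation", {
  # Monte-Carlo against the generator's analytic toward probability:
  # count toward vs away events inside the cue bump across many trains
  cfg <- sim_config()
  cb <- cfg$cue_bias
  frac_toward <- sapply(c("100", "80", "60"), function(rel) {
    set.seed(11)
    pfun <- function(t) 0.5 + cb$gain[[rel]] *
      bias_profile(t, cb$onset, cb$rise, cb$plateau, cb$fall)
    dirs <- unlist(lapply(seq_len(500), function(i) {
      ev <- simulate_microsaccade_train(function(t) rep(40, length(t)), pfun,
                                        600, refractory = 0)
      inb <- ev$time >= cb$onset + cb$rise &
        ev$time <= cb$onset + cb$rise + cb$plateau
      ev$direction[inb]
    }))
    mean(dirs == 1)
  })
  expect_gt(frac_toward[["100"]], frac_toward[["80"]])
  expect_gt(frac_toward[["80"]], frac_toward[["60"]])
  # plateau elevation matches the configured gain to Monte-Carlo precision
  expect_lt(abs(frac_toward[["100"]] - (0.5 + cb$gain[["100"]])), 0.02)
})

test_that("mirrored sessions are exact mirrors through the saccade pipeline", {
  cfg <- sim_config(trials_per_block = 25, reliabilities = "80", seed = 21)
  ses <- simulate_session(cfg, 1)
  mir <- mirror_session(ses)
  expect_equal(mir$gaze$x, -ses$gaze$x)
  ep_a <- epoch_gaze(mask_blinks(ses$gaze), ses$meta$cue_onset, "cue")
  ep_m <- epoch_gaze(mask_blinks(mir$gaze), mir$meta$cue_onset, "cue")
  ev_a <- label_direction(detect_saccades_epochs(ep_a), ses$meta, "cued")
  ev_m <- label_direction(detect_saccades_epochs(ep_m), mir$meta, "cued")
  expect_equal(ev_a$onset, ev_m$onset)
  expect_equal(ev_a$label, ev_m$label)   # labels invariant under full mirror
  expect_true(all(ev_a$direction != ev_m$direction))
})

test_that("clean-blink mode keeps the post-test window artifact-free", {
  cfg <- sim_config(trials_per_block = 60, reliabilities = "80",
                    blink = list(rate = 0.5, duration = 100),
                    clean_blinks = TRUE, seed = 13)
  ses <- simulate_session(cfg, 1)
  mask <- detect_blinks(ses$gaze)
  expect_true(any(mask))  # blinks do exist elsewhere
  for (i in seq_len(nrow(ses$meta))) {
    idx <- (ses$meta$test_onset[i] + 0):(ses$meta$test_onset[i] + 900) + 1
    expect_false(any(mask[idx]))
  }
})

test_that("behavior generator: valid trials are more precise and faster", {
  cfg <- sim_config()
  meta <- data.frame(valid = rep(c(TRUE, FALSE), each = 5000),
                     true_orientation = runif(10000, 0, 180))
  set.seed(31)
  beh <- simulate_behavior(meta, cfg$behavior)
  expect_lt(mean(beh$error[beh$valid]), mean(beh$error[!beh$valid]))
  expect_lt(mean(beh$rt[beh$valid]), mean(beh$rt[!beh$valid]))
  expect_true(all(beh$error >= 0 & beh$error <= 90))
  expect_true(all(beh$score >= 0 & beh$score <= 100))
})

test_that("equal RT parameters across validity remove the RT effect", {
  cfg <- sim_config()
  p <- cfg$behavior
  p$rt_meanlog_invalid <- p$rt_meanlog_valid
  meta <- data.frame(valid = rep(c(TRUE, FALSE), each = 20000),
                     true_orientation = runif(40000, 0, 180))
  set.seed(17)
  beh <- simulate_behavior(meta, p)
  expect_lt(abs(mean(beh$rt[beh$valid]) - mean(beh$rt[!beh$valid])), 0.02)
})

test_that("von Mises noise vanishes at very large concentration", {
  set.seed(3)
  th <- rvonmises(2000, 5e5)
  expect_lt(max(abs(th)), 0.02)
  # moderate kappa: circular mean near 0
  th2 <- rvonmises(20000, 4)
  expect_lt(abs(atan2(mean(sin(th2)), mean(cos(th2)))), 0.05)
})

test_that("EEG generator: zero lateralization gives unit contra/ipsi ratio", {
  cfg <- sim_config(trials_per_block = 60, reliabilities = "80", seed = 4)
  cfg$alpha$lateralization_pct[["80"]] <- 0
  meta <- subset(simulate_session(cfg, 1)$meta, block == "80")
  ep <- simulate_eeg_epochs(cfg, meta, "cue", subject = 1)
  tc <- alpha_lateralization(ep, "cued", posterior_clusters("symmetric"))
  expect_lt(abs(window_average(tc, c(400, 800))), 3)
})

test_that("noise-free amplitude ratio 1:2 yields a -60% power index", {
  # contralateral amplitude a, ipsilateral 2a: (1-4)/(1+4)*100 = -60
  cfg <- sim_config(trials_per_block = 24, reliabilities = "80", seed = 6)
  cfg$alpha$lateralization_pct[["80"]] <- -60
  cfg$alpha$noise_sd <- 0
  meta <- subset(simulate_session(cfg, 1)$meta, block == "80")
  ep <- simulate_eeg_epochs(cfg, meta, "cue", subject = 1)
  tc <- alpha_lateralization(ep, "cued", posterior_clusters("symmetric"))
  expect_lt(abs(window_average(tc, c(400, 800)) - (-60)), 0.5)
})
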