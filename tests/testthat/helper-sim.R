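# shared fixtures, built in code

# Event-level simulation of one condition's test-locked bias curve:
# microsaccade trains with the configured toward-probability bump,
# turned into a toward-minus-away rate curve on the test-locked axis.
sim_test_bias_curve <- function(n_trials, valid, cfg = sim_config(),
                                t_axis = seq(-200, 900)) {
  tb <- cfg$test_bias
  plateau <- tb$plateau + if (!valid) tb$invalid_offset_extension else 0
  # simulate on [0, 1100] ms = epoch time + 200
  pfun <- function(t) {
    0.5 + tb$gain * bias_profile(t, tb$onset + 200, tb$rise, plateau, tb$fall)
  }
  evs <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ev <- simulate_microsaccade_train(function(t) {
      rep(cfg$base_saccade_rate, length(t))
    }, pfun, 1100, main_sequence = cfg$main_sequence)
    if (nrow(ev)) {
      ev$trial <- i
      evs[[i]] <- ev
    }
  }
  ev <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  if (is.null(ev)) {
    return(rep(0, length(t_axis)))
  }
  ev$onset <- ev$time - 200
  ev$label <- ifelse(ev$direction > 0, "toward", "away")
  rate_timecourse(ev, n_trials, t_axis)$bias
}

# A noise-free epoch with a sigmoid gaze step (for detector unit tests).
step_epoch <- function(step_time, amplitude, len = 1500, rise_tau = 0) {
  t <- seq_len(len) - 1
  if (rise_tau <= 0) {
    x <- ifelse(t >= step_time, amplitude, 0)
  } else {
    x <- amplitude * stats::plogis((t - step_time) / rise_tau)
  }
  list(x = x, time = t)
}

# independent, loop-based cluster enumeration oracle (exhaustive sign flips)
enumerate_cluster_p <- function(X, alpha_cluster = 0.05) {
  n <- nrow(X)
  thr <- qt(1 - alpha_cluster / 2, n - 1)
  tmap <- function(M) {
    apply(M, 2, function(col) mean(col) / (sd(col) / sqrt(length(col))))
  }
  masses <- function(tv) {
    out <- c()
    run <- 0
    run_sign <- 0
    for (v in c(tv, 0)) {
      s <- if (!is.na(v) && v > thr) 1 else if (!is.na(v) && v < -thr) -1 else 0
      if (s != 0 && s == run_sign) {
        run <- run + v
      } else {
        if (run_sign != 0) out <- c(out, run)
        run <- if (s != 0) v else 0
        run_sign <- s
      }
    }
    out
  }
  obs <- masses(tmap(X))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  maxm <- apply(signs, 1, function(s) {
    m <- masses(tmap(X * s))
    if (length(m)) max(abs(m)) else 0
  })
  sapply(obs, function(m) mean(maxm >= abs(m)))
}
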