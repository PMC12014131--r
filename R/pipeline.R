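#' Run the full synthetic study pipeline
#'
#' Simulates `cfg$n_subjects` sessions and runs every analysis stage:
#' blink rejection and epoching; saccade detection, labelling, and rate
#' time courses (cue-locked toward the cued item, test-locked toward the
#' tested item); cluster-based permutation tests of the cue-locked bias per
#' reliability and of valid vs invalid test-locked bias; jackknife and
#' fractional-area latency comparisons; trial-count-matched sub-sampling
#' control; alpha-lateralization time courses and window averages (optional);
#' and behavioral summaries with repeated-measures ANOVA, linear trend,
#' paired t-tests and Bayes factors. RT-excluded trials (> 4 s) are removed
#' from all condition averages.
#'
#' @param cfg a [sim_config()].
#' @param n_perm permutations for the cluster tests.
#' @param include_eeg run the alpha-lateralization stages (slowest part).
#' @param clusters electrode clusters for lateralization (default the
#'   as-published definition; see [posterior_clusters()]).
#' @param n_draws sub-sampling draws for the trial-count control.
#' @param cue_window a-priori cue-locked bias window, ms.
#' @param alpha_window a-priori alpha lateralization window, ms.
#' @param verbose print stage progress.
#' @return a results bundle (list) with elements `meta` (config, seed,
#'   config hash), `curves`, `cluster_tests`, `latency`, `subsampling`,
#'   `toward_split`, `alpha`, `behavior`, `log`.
#' @export
run_pipeline <- function(cfg, n_perm = 10000, include_eeg = TRUE,
                         clusters = posterior_clusters(),
                         n_draws = 1000,
                         cue_window = c(200, 600),
                         alpha_window = c(400, 800),
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  rels <- cfg$reliabilities
  t_cue <- seq(epoch_window("cue")[1], epoch_window("cue")[2])
  t_test <- seq(epoch_window("test")[1], epoch_window("test")[2])
  log <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  cue_bias <- lapply(rels, function(r) matrix(NA_real_, cfg$n_subjects,
                                              length(t_cue)))
  names(cue_bias) <- rels
  test_bias <- list()   # [[rel]][[validity]] subject x time
  for (r in rels) test_bias[[r]] <- list(
    valid = matrix(NA_real_, cfg$n_subjects, length(t_test)),
    invalid = matrix(NA_real_, cfg$n_subjects, length(t_test)))
  sub_curves <- list()
  for (r in intersect(rels, c("80", "60"))) {
    sub_curves[[r]] <- matrix(NA_real_, cfg$n_subjects, length(t_test))
  }
  split_curves <- list()  # toward-split: [[rel]][[validity]][[with/without]]
  alpha_curves <- list()
  alpha_win_mean <- matrix(NA_real_, cfg$n_subjects, length(rels),
                           dimnames = list(NULL, rels))
  cue_win_mean <- matrix(NA_real_, cfg$n_subjects, length(rels),
                         dimnames = list(NULL, rels))
  behav_rows <- list()
  events_log <- list()

  for (s in seq_len(cfg$n_subjects)) {
    say("subject %d/%d", s, cfg$n_subjects)
    ses <- simulate_session(cfg, s)
    rec <- mask_blinks(ses$gaze)
    beh <- rt_filter(ses$behavior)
    behav_rows[[s]] <- beh
    for (r in rels) {
      in_block <- which(ses$meta$block == r & beh$included)
      meta_b <- ses$meta[in_block, , drop = FALSE]
      nb <- length(in_block)
      if (nb == 0) stop("pipeline stage epoching: no included trials for ",
                        "subject ", s, " block ", r)
      ep_cue <- epoch_gaze(rec, meta_b$cue_onset, "cue")
      ep_test <- epoch_gaze(rec, meta_b$test_onset, "test")
      ev_cue <- label_direction(detect_saccades_epochs(ep_cue),
                                meta_b, "cued")
      ev_test <- label_direction(detect_saccades_epochs(ep_test),
                                 meta_b, "tested")
      events_log[[paste(s, r)]] <- c(cue = nrow(ev_cue), test = nrow(ev_test))
      rc <- rate_timecourse(ev_cue, nb, t_cue)
      cue_bias[[r]][s, ] <- rc$bias
      cue_win_mean[s, r] <- mean(rc$bias[t_cue >= cue_window[1] &
                                           t_cue <= cue_window[2]])
      iv <- which(!meta_b$valid); vv <- which(meta_b$valid)
      test_bias[[r]]$valid[s, ] <-
        rate_timecourse(ev_test[ev_test$trial %in% vv, , drop = FALSE],
                        length(vv), t_test)$bias
      if (length(iv)) {
        test_bias[[r]]$invalid[s, ] <-
          rate_timecourse(ev_test[ev_test$trial %in% iv, , drop = FALSE],
                          length(iv), t_test)$bias
        if (r %in% names(sub_curves)) {
          sub_curves[[r]][s, ] <- subsample_match(
            ev_test[ev_test$trial %in% vv, , drop = FALSE], vv, length(iv),
            t_test, n_draws = n_draws)$bias
        }
      }
      # toward-split: classify by first cue-locked saccade in the window
      toward <- classify_toward_trials(ev_cue, nb, cue_window)
      for (val in c(TRUE, FALSE)) {
        ids <- which(meta_b$valid == val)
        if (!length(ids)) next
        for (w in c(TRUE, FALSE)) {
          grp <- ids[toward[ids] == w]
          key <- paste(r, if (val) "valid" else "invalid",
                       if (w) "with_toward" else "without_toward", sep = ".")
          if (is.null(split_curves[[key]])) {
            split_curves[[key]] <- matrix(NA_real_, cfg$n_subjects,
                                          length(t_test))
          }
          if (length(grp)) {
            split_curves[[key]][s, ] <- rate_timecourse(
              ev_test[ev_test$trial %in% grp, , drop = FALSE],
              length(grp), t_test)$bias
          }
        }
      }
      if (include_eeg) {
        ep_eeg <- simulate_eeg_epochs(cfg, meta_b, "cue", subject = s)
        tc <- alpha_lateralization(ep_eeg, "cued", clusters)
        if (is.null(alpha_curves[[r]])) {
          alpha_curves[[r]] <- matrix(NA_real_, cfg$n_subjects,
                                      length(tc$time))
          attr(alpha_curves[[r]], "time") <- tc$time
        }
        alpha_curves[[r]][s, ] <- tc$index
        alpha_win_mean[s, r] <- window_average(tc, alpha_window)
      }
    }
  }

  say("group statistics")
  cluster_tests <- list()
  for (r in rels) {
    cluster_tests[[paste0("cue_bias_", r)]] <-
      cluster_permutation_test(cue_bias[[r]], time = t_cue, n_perm = n_perm)
  }
  for (r in intersect(rels, c("80", "60"))) {
    cluster_tests[[paste0("test_valid_", r)]] <-
      cluster_permutation_test(test_bias[[r]]$valid, time = t_test,
                               n_perm = n_perm)
    cluster_tests[[paste0("test_invalid_", r)]] <-
      cluster_permutation_test(test_bias[[r]]$invalid, time = t_test,
                               n_perm = n_perm)
    cluster_tests[[paste0("test_valid_vs_invalid_", r)]] <-
      cluster_permutation_test(test_bias[[r]]$valid, test_bias[[r]]$invalid,
                               time = t_test, n_perm = n_perm)
  }

  latency <- list()
  for (r in intersect(rels, c("80", "60"))) {
    latency[[r]] <- list(
      jackknife = jackknife_latency_compare(
        test_bias[[r]]$invalid, test_bias[[r]]$valid, t_test,
        window = c(0, 900)),
      fal = tryCatch(
        fal_group_compare(test_bias[[r]]$invalid, test_bias[[r]]$valid,
                          t_test, window = c(0, 900)),
        error = function(e) conditionMessage(e)))
  }

  behav <- do.call(rbind, behav_rows)
  bsum <- condition_summary(behav)
  cells <- bsum$cells
  err_mat <- rt_mat <- matrix(NA_real_, cfg$n_subjects, length(rels),
                              dimnames = list(NULL, rels))
  for (r in rels) {
    sub_cells <- cells[cells$block == r, ]
    agg <- stats::aggregate(cbind(error, rt) ~ subject, sub_cells, mean)
    err_mat[agg$subject, r] <- agg$error
    rt_mat[agg$subject, r] <- agg$rt
  }
  behavior_tests <- list(
    error_anova = rm_anova_linear_trend(err_mat),
    rt_anova = rm_anova_linear_trend(rt_mat))
  for (r in intersect(rels, c("80", "60"))) {
    ve <- bsum$validity_effects[bsum$validity_effects$block == r, ]
    if (nrow(ve) >= 2) {
      te <- one_sample_t(ve$error_effect)
      tr_ <- one_sample_t(ve$rt_effect)
      behavior_tests[[paste0("validity_", r)]] <- list(
        error = c(te, list(mean_effect = mean(ve$error_effect),
                           bf01 = jzs_bf01(te$t, nrow(ve))$bf01)),
        rt = c(tr_, list(mean_effect = mean(ve$rt_effect),
                         bf01 = jzs_bf01(tr_$t, nrow(ve))$bf01)))
    }
  }

  anova_tests <- list(
    cue_bias = rm_anova_linear_trend(cue_win_mean),
    alpha = if (include_eeg) rm_anova_linear_trend(alpha_win_mean))

  bundle <- list(
    meta = list(config = cfg, seed = cfg$seed,
                config_hash = config_hash(cfg),
                n_perm = n_perm, timestamp = NULL),
    time = list(cue = t_cue, test = t_test),
    curves = list(cue_bias = cue_bias, test_bias = test_bias),
    cue_win_mean = cue_win_mean,
    alpha = if (include_eeg) list(curves = alpha_curves,
                                  win_mean = alpha_win_mean),
    cluster_tests = cluster_tests,
    latency = latency,
    subsampling = sub_curves,
    toward_split = split_curves,
    behavior = list(table = behav, summary = bsum, tests = behavior_tests),
    anova = anova_tests,
    log = list(events = events_log))
  class(bundle) <- "gazebias_bundle"
  bundle
}

#' Stable hash of a configuration
#'
#' Small content hash (djb2 over the deparsed config) recorded in every
#' output so result files can be traced to their generating configuration.
#' @param cfg a [sim_config()].
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a human-readable report of a results bundle
#'
#' Emits per-figure-style CSVs (group-mean bias curves per condition,
#' lateralization curves, latency and behavior tables, cluster masks) and
#' a plain-text summary of all statistical tests. Every file carries the
#' config hash and seed in a header comment.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  if (is.null(bundle$curves)) stop("incomplete bundle: no curves")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config %s seed %d", bundle$meta$config_hash,
                 bundle$meta$seed)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    con <- file(p, "w"); writeLines(hdr, con); close(con)
    suppressWarnings(utils::write.table(df, p, sep = ",", row.names = FALSE,
                                        append = TRUE))
    paths <<- c(paths, p)
    p
  }
  cue <- data.frame(time = bundle$time$cue)
  for (r in names(bundle$curves$cue_bias)) {
    cue[[paste0("bias_", r)]] <- colMeans(bundle$curves$cue_bias[[r]],
                                          na.rm = TRUE)
  }
  wcsv(cue, "cue_bias_curves.csv")
  tst <- data.frame(time = bundle$time$test)
  for (r in names(bundle$curves$test_bias)) {
    for (v in c("valid", "invalid")) {
      m <- bundle$curves$test_bias[[r]][[v]]
      if (!all(is.na(m))) {
        tst[[paste0("bias_", r, "_", v)]] <- colMeans(m, na.rm = TRUE)
      }
    }
  }
  wcsv(tst, "test_bias_curves.csv")
  if (!is.null(bundle$alpha)) {
    for (r in names(bundle$alpha$curves)) {
      a <- data.frame(time = attr(bundle$alpha$curves[[r]], "time"),
                      index = colMeans(bundle$alpha$curves[[r]],
                                       na.rm = TRUE))
      wcsv(a, paste0("alpha_lateralization_", r, ".csv"))
    }
  }
  lat_rows <- list()
  for (r in names(bundle$latency)) {
    jk <- bundle$latency[[r]]$jackknife
    lat_rows[[r]] <- data.frame(
      block = r,
      onset_delta = jk$onset$delta, onset_t = jk$onset$t,
      onset_p = jk$onset$p,
      offset_delta = jk$offset$delta, offset_t = jk$offset$t,
      offset_p = jk$offset$p)
  }
  if (length(lat_rows)) wcsv(do.call(rbind, lat_rows), "latency_jackknife.csv")
  wcsv(bundle$behavior$summary$group, "behavior_group.csv")
  # text summary
  p <- file.path(dir, "summary.txt")
  con <- file(p, "w")
  writeLines(hdr, con)
  for (nm in names(bundle$cluster_tests)) {
    ct <- bundle$cluster_tests[[nm]]
    if (nrow(ct$clusters)) {
      for (k in seq_len(nrow(ct$clusters))) {
        writeLines(sprintf("%s: cluster [%g, %g] ms mass %.2f p = %.4g", nm,
                           ct$clusters$start_time[k], ct$clusters$end_time[k],
                           ct$clusters$mass[k], ct$clusters$p[k]), con)
      }
    } else writeLines(paste0(nm, ": no clusters"), con)
  }
  for (r in names(bundle$latency)) {
    jk <- bundle$latency[[r]]$jackknife
    writeLines(sprintf(
      "latency %s: onset delta %.1f ms (t=%.2f, p=%.3f), offset delta %.1f ms (t=%.2f, p=%.3f)",
      r, jk$onset$delta, jk$onset$t, jk$onset$p,
      jk$offset$delta, jk$offset$t, jk$offset$p), con)
  }
  close(con)
  paths <- c(paths, p)
  invisible(paths)
}
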