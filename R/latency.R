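#' 50%-of-peak onset and offset latency
#'
#' The onset latency is the first time, before the (positive) peak of the
#' curve inside the search window, at which the curve reaches
#' `fraction` x peak; the offset latency is the first time after the peak
#' at which it drops below `fraction` x peak. Crossings are linearly
#' interpolated between samples. If the curve never falls below the
#' criterion inside the window on one side of the peak, the window edge is
#' returned for that latency.
#'
#' @param time time axis in ms.
#' @param curve bias values (Hz) on `time`.
#' @param fraction fraction of the peak (default 0.5).
#' @param window search window c(start, end) in ms (default full axis).
#' @return list with `onset`, `offset`, `peak_time`, `peak`.
#' @export
peak_fraction_latency <- function(time, curve, fraction = 0.5,
                                  window = range(time)) {
  sel <- which(time >= window[1] & time <= window[2] & !is.na(curve))
  if (!length(sel)) stop("no valid samples in search window")
  tt <- time[sel]; cc <- curve[sel]
  ipk <- which.max(cc)
  peak <- cc[ipk]
  if (!is.finite(peak) || peak <= 0) {
    stop("curve has no positive peak in the search window; latency undefined")
  }
  crit <- fraction * peak
  cross_at <- function(i, j) {
    # time where the segment [i, j] crosses crit
    tt[i] + (crit - cc[i]) / (cc[j] - cc[i]) * (tt[j] - tt[i])
  }
  # onset: last sample before the peak strictly below the criterion
  below <- which(cc[seq_len(ipk)] < crit)
  onset <- if (length(below)) cross_at(max(below), max(below) + 1) else tt[1]
  # offset: first sample after the peak strictly below the criterion
  after <- which(cc[ipk:length(cc)] < crit)
  offset <- if (length(after)) {
    j <- ipk + min(after) - 1
    cross_at(j - 1, j)
  } else tt[length(tt)]
  list(onset = onset, offset = offset, peak_time = tt[ipk], peak = peak)
}

#' Fractional-area onset and offset latency
#'
#' Area is accumulated above a noise `floor` (values below the floor
#' contribute nothing): each sample spans [t, t + dt) and contributes
#' max(curve - floor, 0) * dt, so the cumulative area is piecewise linear
#' in time. Onset/offset are the times where the cumulative area first
#' reaches `fractions[1]` / `fractions[2]` of the total, linearly
#' interpolated. A curve that never exceeds the floor has zero area and is
#' flagged rather than given a latency.
#'
#' @param time time axis in ms (uniform grid).
#' @param curve bias values (Hz).
#' @param fractions area fractions for onset and offset (default 0.25, 0.75).
#' @param floor lower boundary in Hz (default 0.3).
#' @param window search window in ms.
#' @return list with `onset`, `offset`, `area` (Hz*ms) and `zero_area`
#'   (TRUE when the curve never exceeds the floor; latencies are NA then).
#' @export
fractional_area_latency <- function(time, curve, fractions = c(0.25, 0.75),
                                    floor = 0.3, window = range(time)) {
  sel <- which(time >= window[1] & time <= window[2] & !is.na(curve))
  if (!length(sel)) stop("no valid samples in search window")
  tt <- time[sel]; cc <- curve[sel]
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  clamped <- pmax(cc - floor, 0)
  total <- sum(clamped) * dt
  if (total <= 0) {
    return(list(onset = NA_real_, offset = NA_real_, area = 0,
                zero_area = TRUE))
  }
  cum <- c(0, cumsum(clamped) * dt)     # cum[k] = area before sample k
  latency_at <- function(frac) {
    target <- frac * total
    k <- which(cum[-1] >= target)[1]    # target reached within sample k
    if (clamped[k] == 0) return(tt[k])
    tt[k] + (target - cum[k]) / clamped[k]  # clamped[k] * dt per dt
  }
  list(onset = latency_at(fractions[1]), offset = latency_at(fractions[2]),
       area = total, zero_area = FALSE)
}

#' Jackknife latency comparison between two conditions
#'
#' Computes 50%-of-peak (or fractional-area) onset/offset latencies on each
#' leave-one-subject-out grand-average curve of conditions A and B, and
#' tests the condition difference with the jackknife-corrected paired t
#' statistic: the variance of the leave-one-out differences is rescaled by
#' (n-1)^2 (equivalently, SE = sqrt((n-1)/n * sum((d_i - dbar)^2))),
#' correcting for the dependence the subsampling induces.
#'
#' @param curves_a,curves_b subjects x time matrices (same subjects, n >= 3).
#' @param time time axis in ms.
#' @param fraction peak fraction (for `method = "peak50"`).
#' @param window search window in ms.
#' @param method `"peak50"` or `"fal"`.
#' @param ... passed to the latency function (e.g. `floor`, `fractions`).
#' @return list with per-measure (`onset`, `offset`) lists containing
#'   `delta` (A - B on the full grand averages), `delta_loo` (mean of
#'   leave-one-out differences), `t` (jackknife-corrected), `df`, `p`,
#'   `se`, and the per-subsample differences `loo`.
#' @export
jackknife_latency_compare <- function(curves_a, curves_b, time,
                                      fraction = 0.5, window = range(time),
                                      method = c("peak50", "fal"), ...) {
  method <- match.arg(method)
  stopifnot(nrow(curves_a) == nrow(curves_b), ncol(curves_a) == length(time))
  n <- nrow(curves_a)
  if (n < 3) stop("need at least 3 subjects")
  lat_fn <- function(curve) {
    if (method == "peak50") {
      peak_fraction_latency(time, curve, fraction, window)
    } else {
      fractional_area_latency(time, curve, window = window, ...)
    }
  }
  loo_lat <- function(curves, drop) {
    ga <- colMeans(curves[-drop, , drop = FALSE])
    out <- tryCatch(lat_fn(ga), error = function(e) {
      stop("undefined latency for leave-one-out subsample dropping subject ",
           drop, ": ", conditionMessage(e))
    })
    if (isTRUE(out$zero_area)) {
      stop("zero area for leave-one-out subsample dropping subject ", drop)
    }
    out
  }
  la <- lapply(seq_len(n), function(i) loo_lat(curves_a, i))
  lb <- lapply(seq_len(n), function(i) loo_lat(curves_b, i))
  full_a <- lat_fn(colMeans(curves_a))
  full_b <- lat_fn(colMeans(curves_b))
  one <- function(field) {
    d <- vapply(seq_len(n), function(i) la[[i]][[field]] - lb[[i]][[field]],
                numeric(1))
    dbar <- mean(d)
    se <- sqrt((n - 1) / n * sum((d - dbar)^2))
    t_stat <- if (se > 0) dbar / se else if (dbar == 0) 0 else sign(dbar) * Inf
    p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), n - 1)
         else if (t_stat == 0) 1 else 0
    list(delta = full_a[[field]] - full_b[[field]], delta_loo = dbar,
         t = t_stat, df = n - 1, p = p, se = se, loo = d)
  }
  list(onset = one("onset"), offset = one("offset"), method = method, n = n)
}

#' Group fractional-area latency comparison
#'
#' Per-subject fractional-area latencies in two conditions, compared with a
#' paired t-test over the subjects whose curves have positive area above
#' the floor in both conditions; zero-area subjects are excluded and
#' counted.
#'
#' @inheritParams jackknife_latency_compare
#' @param fractions area fractions (default c(0.25, 0.75)).
#' @param floor noise floor in Hz (default 0.3).
#' @return list with per-measure test results (`delta` = mean A - B, `t`,
#'   `df`, `p`, per-subject latencies) plus `n_excluded` and `excluded`.
#' @export
fal_group_compare <- function(curves_a, curves_b, time,
                              fractions = c(0.25, 0.75), floor = 0.3,
                              window = range(time)) {
  n <- nrow(curves_a)
  fa <- lapply(seq_len(n), function(i) {
    fractional_area_latency(time, curves_a[i, ], fractions, floor, window)
  })
  fb <- lapply(seq_len(n), function(i) {
    fractional_area_latency(time, curves_b[i, ], fractions, floor, window)
  })
  ok <- !vapply(fa, `[[`, logical(1), "zero_area") &
        !vapply(fb, `[[`, logical(1), "zero_area")
  if (sum(ok) < 2) stop("fewer than 2 subjects with non-zero area")
  one <- function(field) {
    a <- vapply(fa[ok], `[[`, numeric(1), field)
    b <- vapply(fb[ok], `[[`, numeric(1), field)
    tt <- stats::t.test(a, b, paired = TRUE)
    list(delta = mean(a - b), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         latencies_a = a, latencies_b = b)
  }
  list(onset = one("onset"), offset = one("offset"),
       n_included = sum(ok), n_excluded = sum(!ok), excluded = which(!ok))
}
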