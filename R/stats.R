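#' One-sample and paired t-tests
#'
#' Thin wrappers around [stats::t.test()] returning (t, df, p) as used
#' inside cluster formation and for window-averaged contrasts.
#'
#' @param x numeric values (one-sample: tested against `mu`).
#' @param y for [paired_t()], the paired condition.
#' @param mu null value (one-sample).
#' @return list(t, df, p).
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) stop("need n >= 2")
  if (stats::sd(x) == 0) stop("zero variance: t undefined")
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  one_sample_t(x - y)
}

#' Columnwise t statistics with sign-flip reuse
#' @keywords internal
.col_t <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[v <= 0] <- NA
  t
}

#' Clusters of supra-threshold same-sign t values
#' @keywords internal
.cluster_masses <- function(t, thr) {
  state <- integer(length(t))
  state[!is.na(t) & t > thr] <- 1L
  state[!is.na(t) & t < -thr] <- -1L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  }
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep),
                           function(k) sum(t[starts[k]:ends[k]]), numeric(1)))
}

#' Cluster-based permutation test on time courses
#'
#' One-sample mode tests subject time courses against zero by random sign
#' flipping; paired mode tests A - B by random condition swaps per subject
#' (equivalently sign flips of the difference). Clusters are maximal runs
#' of temporally adjacent points whose t values share a sign and exceed the
#' two-sided `alpha_cluster` threshold; cluster mass is the sum of t values.
#' The null distribution is the maximum absolute cluster mass per
#' permutation, and each observed cluster's p-value is
#' (1 + #\{permutation max >= |mass|\}) / (n_perm + 1), so p > 0 always.
#' Zero-variance time points have undefined t and are treated as
#' sub-threshold (their count is reported).
#'
#' @param x subjects x time matrix.
#' @param y optional second condition (paired, same subjects/order).
#' @param time optional time axis for reporting cluster extents.
#' @param n_perm number of random permutations (default 10000).
#' @param alpha_cluster two-sided cluster-forming alpha (default 0.05).
#' @param seed optional integer seed for the permutation RNG.
#' @return object of class `cluster_result`: list(clusters = data.frame
#'   (start, end, start_time, end_time, mass, p), sig_mask, t, thr,
#'   n_perm, n_degenerate).
#' @export
cluster_permutation_test <- function(x, y = NULL, time = NULL,
                                     n_perm = 10000, alpha_cluster = 0.05,
                                     seed = NULL) {
  X <- as.matrix(x)
  if (!is.null(y)) {
    Y <- as.matrix(y)
    stopifnot(identical(dim(X), dim(Y)))
    X <- X - Y
  }
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(time)) time <- seq_len(ncol(X))
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  t_obs <- .col_t(X)
  n_degenerate <- sum(is.na(t_obs))
  obs <- .cluster_masses(t_obs, thr)
  # permutation null: max |mass|; reuse colSums(X^2), only means change
  ss <- colSums(X^2)
  max_mass <- numeric(n_perm)
  block <- 2000L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    M <- (S %*% X) / n
    V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
    V[V < 0] <- 0                       # guard float cancellation
    Tm <- suppressWarnings(M / sqrt(V / n))
    Tm[!is.finite(Tm)] <- NA
    for (b in seq_len(nb)) {
      cm <- .cluster_masses(Tm[b, ], thr)
      max_mass[done + b] <- if (nrow(cm)) max(abs(cm$mass)) else 0
    }
    done <- done + nb
  }
  if (nrow(obs)) {
    obs$p <- vapply(obs$mass, function(m) {
      (1 + sum(max_mass >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    obs$start_time <- time[obs$start]
    obs$end_time <- time[obs$end]
  } else {
    obs$p <- numeric(0)
    obs$start_time <- numeric(0)
    obs$end_time <- numeric(0)
  }
  sig_mask <- rep(FALSE, ncol(X))
  for (k in seq_len(nrow(obs))) {
    if (obs$p[k] < 0.05) sig_mask[obs$start[k]:obs$end[k]] <- TRUE
  }
  structure(list(clusters = obs, sig_mask = sig_mask, t = t_obs, thr = thr,
                 time = time, n_perm = n_perm,
                 alpha_cluster = alpha_cluster,
                 n_degenerate = n_degenerate,
                 mode = if (is.null(y)) "onesample" else "paired"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$mode, ", ", x$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters)) {
    for (k in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: [%g, %g] ms, mass %.2f, p = %.4g\n", k,
                  x$clusters$start_time[k], x$clusters$end_time[k],
                  x$clusters$mass[k], x$clusters$p[k]))
    }
  } else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' One-way repeated-measures ANOVA with linear trend
#'
#' Within-subject one-way ANOVA (subjects x conditions, complete and
#' balanced) plus the linear trend over the ordered conditions, tested via
#' the orthogonal-polynomial contrast applied per subject (one-sample t on
#' the contrast scores; F = t^2 with df 1, n - 1). Effect sizes are partial
#' eta squared.
#'
#' @param mat subjects x conditions matrix; columns in the intended order.
#' @return list(F_main, df_main, p_main, eta2_main, F_linear, df_linear,
#'   p_linear, eta2_linear).
#' @export
rm_anova_linear_trend <- function(mat) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("missing cells: repeated-measures table must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 2) stop("need >= 2 subjects and >= 2 conditions")
  df_long <- data.frame(y = as.vector(mat),
                        subj = factor(rep(seq_len(n), k)),
                        cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ cond + Error(subj), data = df_long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- tab["cond", "Sum Sq"]; ss_err <- tab["Residuals", "Sum Sq"]
  f_main <- tab["cond", "F value"]; p_main <- tab["cond", "Pr(>F)"]
  df_main <- c(tab["cond", "Df"], tab["Residuals", "Df"])
  # linear trend: orthogonal polynomial contrast per subject
  cvec <- stats::contr.poly(k)[, 1]
  L <- as.vector(mat %*% cvec)
  tt <- stats::t.test(L)
  f_lin <- unname(tt$statistic)^2
  list(F_main = f_main, df_main = df_main, p_main = p_main,
       eta2_main = ss_cond / (ss_cond + ss_err),
       F_linear = f_lin, df_linear = c(1, n - 1), p_linear = tt$p.value,
       eta2_linear = f_lin / (f_lin + n - 1))
}

#' JZS (default-prior) Bayes factor for a t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor for a one-sample or
#' paired t-test by numerical integration over the Cauchy effect-size prior
#' (scale `prior_scale`), and returns support for the null, BF01 = 1/BF10.
#'
#' @param t observed t statistic (finite).
#' @param n sample size (pairs for a paired design), n >= 2.
#' @param prior_scale Cauchy prior scale r (default sqrt(2)/2).
#' @param rel_tol relative tolerance of the quadrature.
#' @return list(bf01, bf10, t, n, prior_scale).
#' @export
jzs_bf01 <- function(t, n, prior_scale = sqrt(2) / 2, rel_tol = 1e-8) {
  if (!is.finite(t)) stop("t must be finite")
  if (n < 2) stop("need n >= 2")
  nu <- n - 1
  r2 <- prior_scale^2
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    lg <- -0.5 * log1p(n * r2 * g) -
      (nu + 1) / 2 * log1p(t^2 / (nu * (1 + n * r2 * g))) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) - log_den
    exp(lg)
  }
  bf10 <- stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                           subdivisions = 500L)$value
  list(bf01 = 1 / bf10, bf10 = bf10, t = t, n = n, prior_scale = prior_scale)
}

#' Trial-count-matched sub-sampling of a bias time course
#'
#' Controls for unequal trial counts between conditions: repeatedly draws
#' `n_target` trials without replacement from the larger condition's
#' trials, computes the toward/away bias time course of each draw, and
#' averages the curves across draws.
#'
#' @param events labelled saccade events of the larger condition
#'   (columns `trial`, `onset`, `label`).
#' @param trial_ids vector of that condition's trial indices (the sampling
#'   frame; includes trials without any event).
#' @param n_target number of trials to draw (<= length(trial_ids)).
#' @param time time axis in ms.
#' @param n_draws number of random sub-samples (default 1000).
#' @param window rate window in ms.
#' @param seed optional RNG seed.
#' @return a `rate_timecourse` with the draw-averaged toward, away and bias.
#' @export
subsample_match <- function(events, trial_ids, n_target, time,
                            n_draws = 1000, window = 50, seed = NULL) {
  if (n_target > length(trial_ids)) {
    stop("n_target exceeds the number of available trials")
  }
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, 3, length(time))
  for (d in seq_len(n_draws)) {
    pick <- sample(trial_ids, n_target)
    sub <- events[events$trial %in% pick, , drop = FALSE]
    rc <- rate_timecourse(sub, n_target, time, window)
    acc <- acc + rbind(rc$toward, rc$away, rc$bias)
  }
  acc <- acc / n_draws
  out <- data.frame(time = time, toward = acc[1, ], away = acc[2, ],
                    bias = acc[3, ])
  class(out) <- c("rate_timecourse", "data.frame")
  out
}
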