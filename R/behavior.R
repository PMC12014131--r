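#' Orientation reproduction error
#'
#' Absolute circular difference between reported and true orientation on
#' the 180-degree orientation space; ranges from 0 to 90 degrees.
#'
#' @param reported,true orientations in degrees, in (0, 180].
#' @return error in degrees, [0, 90].
#' @export
reproduction_error <- function(reported, true) {
  if (any(reported <= 0 | reported > 180, na.rm = TRUE) ||
      any(true <= 0 | true > 180, na.rm = TRUE)) {
    stop("orientations must lie in (0, 180] degrees")
  }
  d <- abs(reported - true) %% 180
  pmin(d, 180 - d)
}

#' Feedback score from reproduction error
#'
#' Linear mapping with 100 at zero error and 0 at the maximum error of
#' 90 degrees.
#'
#' @param error reproduction error in degrees, [0, 90].
#' @return score in [0, 100].
#' @export
feedback_score <- function(error) {
  if (any(error < 0 | error > 90, na.rm = TRUE)) {
    stop("error must lie in [0, 90] degrees")
  }
  100 * (1 - error / 90)
}

#' Exclude slow-response trials
#'
#' Marks trials with RT strictly longer than the cutoff as excluded
#' (`included = FALSE`); an RT exactly at the cutoff is retained.
#'
#' @param table behavior table with an `rt` column (seconds).
#' @param cutoff RT cutoff in seconds (default 4).
#' @return the table with an `included` logical column.
#' @export
rt_filter <- function(table, cutoff = 4) {
  if (any(table$rt < 0, na.rm = TRUE)) stop("negative RT")
  table$included <- table$rt <= cutoff
  table
}

#' Condition summaries of behavioral performance
#'
#' Per-subject mean reproduction error and RT per block x validity cell
#' (after RT filtering), group means with SEM, and per-subject validity
#' effects (invalid minus valid) for blocks that contain invalid trials.
#'
#' @param table behavior table (possibly multiple subjects) with columns
#'   `subject`, `block`, `valid`, `error`, `rt` and (optionally)
#'   `included` from [rt_filter()].
#' @return list with `cells` (subject x block x validity means), `group`
#'   (group mean and SEM per cell), and `validity_effects` (per subject
#'   and block: invalid - valid for error and rt).
#' @export
condition_summary <- function(table) {
  if (!nrow(table)) stop("empty behavior table")
  if (is.null(table$included)) table <- rt_filter(table)
  tab <- table[table$included, , drop = FALSE]
  cells <- stats::aggregate(cbind(error, rt) ~ subject + block + valid,
                            data = tab, FUN = mean)
  if (nrow(cells) == 0) stop("no included trials")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  group <- stats::aggregate(cbind(error, rt) ~ block + valid, data = cells,
                            FUN = mean)
  gsem <- stats::aggregate(cbind(error, rt) ~ block + valid, data = cells,
                           FUN = sem)
  names(gsem)[names(gsem) == "error"] <- "error_sem"
  names(gsem)[names(gsem) == "rt"] <- "rt_sem"
  group <- merge(group, gsem, by = c("block", "valid"))
  v <- cells[cells$valid, c("subject", "block", "error", "rt")]
  iv <- cells[!cells$valid, c("subject", "block", "error", "rt")]
  ve <- merge(v, iv, by = c("subject", "block"),
              suffixes = c("_valid", "_invalid"))
  if (nrow(ve)) {
    ve$error_effect <- ve$error_invalid - ve$error_valid
    ve$rt_effect <- ve$rt_invalid - ve$rt_valid
  }
  list(cells = cells, group = group, validity_effects = ve)
}
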