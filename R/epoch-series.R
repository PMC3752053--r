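#' Epoch-level activity series
#'
#' An `epoch_series` is a tibble holding one child's contiguous
#' accelerometer recording: one row per epoch with the epoch start `time`
#' (POSIXct, UTC), non-negative integer activity `counts` and `steps`.
#' The epoch length in seconds is carried as the `epoch_seconds`
#' attribute. Timestamps are implied by `start_time + index * epoch_seconds`
#' and are strictly increasing with no gaps: a loaded series never contains
#' missing rows.
#'
#' @param child_id Single identifier for the child.
#' @param start_time Timestamp (POSIXct or ISO-8601 string, UTC) of the
#'   first epoch.
#' @param epoch_seconds Epoch length in seconds; must divide 60 (15 s and
#'   60 s are the lengths used in practice).
#' @param counts Integer vector of activity counts per epoch.
#' @param steps Integer vector of step counts per epoch, same length as
#'   `counts`.
#'
#' @return A tibble of class `epoch_series` with columns `child_id`,
#'   `time`, `counts`, `steps` and attribute `epoch_seconds`.
#' @examples
#' es <- epoch_series("c1", "2008-06-02 07:00:00", 15,
#'                    counts = c(0, 10, 20, 0), steps = c(0, 1, 2, 0))
#' epoch_length(es)
#' @export
epoch_series <- function(child_id, start_time, epoch_seconds, counts, steps) {
  if (length(counts) < 1L || length(counts) != length(steps)) {
    abort("`counts` and `steps` must have equal length >= 1.",
          class = "accel_data_error")
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0 || 60L %% as.integer(epoch_seconds) != 0L) {
    abort("`epoch_seconds` must be a positive divisor of 60.",
          class = "accel_argument_error")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(is.na(steps)) ||
      any(steps < 0)) {
    abort("counts and steps must be non-negative and non-missing.",
          class = "accel_data_error")
  }
  start_time <- as.POSIXct(start_time, tz = "UTC")
  if (is.na(start_time)) {
    abort("`start_time` is not a parseable timestamp.",
          class = "accel_format_error")
  }
  n <- length(counts)
  out <- tibble::tibble(
    child_id = as.character(child_id),
    time = start_time + (seq_len(n) - 1L) * as.numeric(epoch_seconds),
    counts = as.numeric(counts),
    steps = as.numeric(steps)
  )
  new_epoch_series(out, as.integer(epoch_seconds))
}

new_epoch_series <- function(tbl, epoch_seconds) {
  attr(tbl, "epoch_seconds") <- as.integer(epoch_seconds)
  class(tbl) <- unique(c("epoch_series", class(tbl)))
  tbl
}

#' Epoch length of a series
#'
#' @param series An [epoch_series()].
#' @return Epoch length in seconds (integer).
#' @export
epoch_length <- function(series) {
  es <- attr(series, "epoch_seconds")
  if (is.null(es)) abort("not an epoch_series (missing epoch_seconds).",
                         class = "accel_argument_error")
  es
}

#' Re-integrate a series to a coarser epoch length
#'
#' Sums counts and steps over consecutive blocks of epochs to produce a
#' series at a coarser grain, e.g. 15 s recordings re-integrated to the
#' 60 s epochs on which counts-per-minute thresholds are defined. A
#' trailing partial block is dropped; the dropped epochs and their count
#' and step totals are recorded in the `dropped` attribute of the result,
#' so totals are conserved up to the logged remainder.
#'
#' @param series An [epoch_series()].
#' @param target_epoch_seconds Target epoch length; must be a positive
#'   multiple of the series' epoch length.
#' @return An `epoch_series` at the target grain, with attribute
#'   `dropped` (list with `n_epochs`, `counts`, `steps`).
#' @examples
#' es <- epoch_series("c1", "2008-06-02 07:00:00", 15,
#'                    counts = c(10, 20, 30, 40), steps = c(1, 2, 3, 4))
#' reintegrate(es, 60)$counts  # 100
#' @export
reintegrate <- function(series, target_epoch_seconds) {
  es <- epoch_length(series)
  target_epoch_seconds <- as.integer(target_epoch_seconds)
  if (length(target_epoch_seconds) != 1L || is.na(target_epoch_seconds) ||
      target_epoch_seconds <= 0L || target_epoch_seconds %% es != 0L) {
    abort("`target_epoch_seconds` must be a positive multiple of the series epoch length.",
          class = "accel_argument_error")
  }
  k <- target_epoch_seconds %/% es
  if (k == 1L) {
    attr(series, "dropped") <- list(n_epochs = 0L, counts = 0, steps = 0)
    return(series)
  }
  n <- nrow(series)
  n_full <- n %/% k
  if (n_full == 0L) {
    abort("series is shorter than one target epoch.",
          class = "accel_argument_error")
  }
  keep <- seq_len(n_full * k)
  dropped_idx <- setdiff(seq_len(n), keep)
  block <- rep(seq_len(n_full), each = k)
  out <- tibble::tibble(
    child_id = series$child_id[1L],
    time = series$time[seq(1L, by = k, length.out = n_full)],
    counts = as.numeric(tapply(series$counts[keep], block, sum)),
    steps = as.numeric(tapply(series$steps[keep], block, sum))
  )
  out <- new_epoch_series(out, target_epoch_seconds)
  attr(out, "dropped") <- list(
    n_epochs = length(dropped_idx),
    counts = sum(series$counts[dropped_idx]),
    steps = sum(series$steps[dropped_idx])
  )
  if (length(dropped_idx) > 0L) {
    inform(sprintf("reintegrate: dropped %d trailing partial epoch(s) (%g counts, %g steps).",
                   length(dropped_idx), attr(out, "dropped")$counts,
                   attr(out, "dropped")$steps),
           class = "accel_reintegrate_drop")
  }
  out
}
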