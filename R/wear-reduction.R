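#' Reduction rule configuration
#'
#' Bundles the cleaning and validity thresholds applied to epoch-level
#' recordings. Defaults are the standard child-cohort processing rules:
#' spurious counts at >= 11715 counts/min, non-wear as runs of >= 20 min of
#' consecutive zero counts, wear days requiring >= 150 registered minutes
#' within the 07:00--21:59 waking window, valid days requiring >= 10 h of
#' registered time over the whole day, and inclusion requiring >= 2 valid
#' days. All boundaries are inclusive.
#'
#' @param spurious_cpm Counts/min at or above which an epoch is spurious.
#' @param nonwear_min_minutes Minimum length (minutes) of a consecutive
#'   zero-count run classed as non-wear.
#' @param wearday_min_minutes Minimum waking-window registered minutes for
#'   a day to count as a wear day (start/end detection).
#' @param validday_min_hours Minimum registered hours (whole day) for a
#'   valid day.
#' @param min_valid_days Minimum number of valid days for a child to be
#'   included.
#' @param waking_start,waking_end Clock times ("HH:MM") bounding the
#'   waking window; the window is inclusive of both named minutes.
#' @param nonwear_tolerance_minutes Minutes of non-zero interruption
#'   tolerated inside a non-wear run. The consecutive-zero rule is
#'   literal, so the default is 0; the knob exists to probe sensitivity.
#' @return A list of class `reduction_config`.
#' @export
reduction_config <- function(spurious_cpm = 11715,
                             nonwear_min_minutes = 20,
                             wearday_min_minutes = 150,
                             validday_min_hours = 10,
                             min_valid_days = 2,
                             waking_start = "07:00",
                             waking_end = "21:59",
                             nonwear_tolerance_minutes = 0) {
  assert_number(spurious_cpm, "spurious_cpm")
  assert_number(nonwear_min_minutes, "nonwear_min_minutes")
  assert_number(wearday_min_minutes, "wearday_min_minutes")
  assert_number(validday_min_hours, "validday_min_hours")
  assert_number(min_valid_days, "min_valid_days")
  ws <- parse_clock(waking_start)
  we <- parse_clock(waking_end)
  if (ws >= we) {
    abort("waking window start must precede its end within a day.",
          class = "accel_argument_error")
  }
  if (!is.numeric(nonwear_tolerance_minutes) || nonwear_tolerance_minutes < 0) {
    abort("`nonwear_tolerance_minutes` must be >= 0.",
          class = "accel_argument_error")
  }
  structure(
    list(spurious_cpm = spurious_cpm,
         nonwear_min_minutes = nonwear_min_minutes,
         wearday_min_minutes = wearday_min_minutes,
         validday_min_hours = validday_min_hours,
         min_valid_days = min_valid_days,
         waking_start_minute = ws,
         waking_end_minute = we,
         nonwear_tolerance_minutes = nonwear_tolerance_minutes),
    class = "reduction_config"
  )
}

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1L]]
  if (length(m) != 3L) {
    abort(sprintf("'%s' is not a clock time (HH:MM).", x),
          class = "accel_argument_error")
  }
  as.integer(m[2L]) * 60L + as.integer(m[3L])
}

require_minute_epochs <- function(series, what) {
  if (epoch_length(series) != 60L) {
    abort(sprintf("%s operates on 60 s epochs; reintegrate() the series first (counts/min thresholds are defined per minute).",
                  what),
          class = "accel_argument_error")
  }
  invisible(series)
}

#' Flag spurious epochs
#'
#' Labels every 60 s epoch with counts at or above the spurious threshold
#' (default >= 11715 counts/min) as `SPURIOUS`. Spurious epochs are removed
#' from analysis entirely: they contribute to neither count totals nor
#' registered wear time, and they break zero-count runs for non-wear
#' detection (a spurious epoch is not a zero).
#'
#' @param series An [epoch_series()] at 60 s epochs.
#' @param config A [reduction_config()].
#' @return The series with a `wear` factor column
#'   (`WORN`/`NONWEAR`/`SPURIOUS`); the number flagged is in attribute
#'   `n_spurious`.
#' @export
flag_spurious <- function(series, config = reduction_config()) {
  require_minute_epochs(series, "flag_spurious()")
  series$wear <- factor(ifelse(series$counts >= config$spurious_cpm,
                               "SPURIOUS", "WORN"),
                        levels = wear_levels())
  out <- new_epoch_series(series, 60L)
  attr(out, "n_spurious") <- sum(out$wear == "SPURIOUS")
  out
}

wear_levels <- function() c("WORN", "NONWEAR", "SPURIOUS")

#' Detect non-wear bouts
#'
#' Relabels every maximal run of consecutive zero-count `WORN` epochs
#' lasting at least `nonwear_min_minutes` (default 20 min, inclusive) as
#' `NONWEAR`. Runs are detected over the whole series, so a run spanning
#' midnight is assessed once against the 20-min rule even though day
#' accounting later splits it at midnight. Spurious epochs must already be
#' flagged; they terminate zero runs. The operation is idempotent.
#'
#' @param series An [epoch_series()] at 60 s epochs carrying a `wear`
#'   column (from [flag_spurious()]); if absent, all epochs are treated
#'   as worn.
#' @param config A [reduction_config()].
#' @return The series with its `wear` column updated.
#' @export
detect_nonwear <- function(series, config = reduction_config()) {
  require_minute_epochs(series, "detect_nonwear()")
  if (is.null(series$wear)) {
    series$wear <- factor(rep("WORN", nrow(series)), levels = wear_levels())
    series <- new_epoch_series(series, 60L)
  }
  zero_worn <- series$counts == 0 & series$wear == "WORN"
  tol <- config$nonwear_tolerance_minutes
  if (tol > 0) {
    zero_worn <- bridge_short_interruptions(zero_worn,
                                            series$wear == "WORN", tol)
  }
  r <- rle(zero_worn)
  long_run <- r$values & r$lengths >= config$nonwear_min_minutes
  relabel <- inverse.rle(list(values = long_run, lengths = r$lengths))
  series$wear[relabel] <- "NONWEAR"
  new_epoch_series(series, 60L)
}

# Treat runs of <= tol non-zero worn minutes sandwiched between zero-count
# worn minutes as part of the surrounding zero run.
bridge_short_interruptions <- function(zero_worn, worn, tol) {
  r <- rle(zero_worn)
  n_runs <- length(r$lengths)
  if (n_runs < 3L) return(zero_worn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq(2L, n_runs - 1L)) {
    if (!r$values[i] && r$lengths[i] <= tol &&
        r$values[i - 1L] && r$values[i + 1L] &&
        all(worn[starts[i]:ends[i]])) {
      r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Per-day wear accounting
#'
#' Collapses a masked series into one record per calendar date spanned:
#' registered (worn) minutes for the whole day and within the waking
#' window, and count and step totals accumulated over `WORN` epochs only.
#' Non-wear and spurious epochs contribute to nothing. Wear-day and
#' valid-day flags are evaluated here; exclusion bookkeeping is completed
#' by [select_valid()].
#'
#' @param series An [epoch_series()] at 60 s epochs with a finalized
#'   `wear` column.
#' @param config A [reduction_config()].
#' @return A tibble with one row per date: `child_id`, `date`,
#'   `registered_minutes`, `waking_registered_minutes`, `counts_sum`,
#'   `steps_sum`, `n_spurious`, `is_wear_day`, `is_valid_day`,
#'   `exclusion_reason`.
#' @export
registered_time <- function(series, config = reduction_config()) {
  require_minute_epochs(series, "registered_time()")
  if (is.null(series$wear)) {
    abort("series has no wear mask; run flag_spurious()/detect_nonwear() first.",
          class = "accel_argument_error")
  }
  secs <- as.numeric(series$time)  # UTC, so day arithmetic is plain modulo
  minute_of_day <- (secs %% 86400) %/% 60
  waking <- minute_of_day >= config$waking_start_minute &
    minute_of_day <= config$waking_end_minute
  worn <- series$wear == "WORN"
  days <- tibble::tibble(
    child_id = series$child_id,
    date = as.Date(secs %/% 86400, origin = "1970-01-01"),
    worn = worn,
    waking_worn = worn & waking,
    counts = ifelse(worn, series$counts, 0),
    steps = ifelse(worn, series$steps, 0),
    spurious = series$wear == "SPURIOUS"
  )
  out <- dplyr::summarise(
    dplyr::group_by(days, .data$child_id, .data$date),
    registered_minutes = sum(.data$worn),
    waking_registered_minutes = sum(.data$waking_worn),
    counts_sum = sum(.data$counts),
    steps_sum = sum(.data$steps),
    n_spurious = sum(.data$spurious),
    .groups = "drop"
  )
  dplyr::mutate(
    out,
    is_wear_day = .data$waking_registered_minutes >= config$wearday_min_minutes,
    is_valid_day = .data$is_wear_day &
      .data$registered_minutes >= config$validday_min_hours * 60,
    exclusion_reason = ifelse(.data$registered_minutes == 0, "no_wear", "")
  )
}

#' Detect the wear period start and end dates
#'
#' The first and last calendar days whose waking-window registered time
#' reaches the wear-day threshold (default >= 150 min within 07:00--21:59)
#' delimit the observation period; days outside it (e.g. postal-transit
#' days) are excluded. If no day reaches the threshold the interval is
#' empty and the child cannot be included.
#'
#' @param days Day records from [registered_time()].
#' @param config A [reduction_config()].
#' @return One-row tibble with `start_date` and `end_date` (`NA` dates
#'   for an empty interval).
#' @export
detect_start_end <- function(days, config = reduction_config()) {
  ok <- days$waking_registered_minutes >= config$wearday_min_minutes
  if (!any(ok)) {
    return(tibble::tibble(start_date = as.Date(NA), end_date = as.Date(NA)))
  }
  d <- sort(days$date[ok])
  tibble::tibble(start_date = d[1L], end_date = d[length(d)])
}

#' Select valid days and decide child inclusion
#'
#' Applies the start/end interval, flags valid days (registered time >=
#' `validday_min_hours`, default 10 h, on a wear day inside the interval)
#' and decides inclusion (>= `min_valid_days` valid days, default 2).
#' Every excluded day and excluded child carries a machine-readable
#' reason so an exclusion flow table can be reconciled against totals.
#'
#' @param days Day records from [registered_time()].
#' @param config A [reduction_config()].
#' @param interval Optional interval from [detect_start_end()]; computed
#'   from `days` when omitted.
#' @return The day tibble with `is_valid_day` and `exclusion_reason`
#'   finalized, plus attributes `child_included` (flag) and
#'   `child_exclusion_reason` (`""`, `"no_wear_days"` or
#'   `"insufficient_valid_days"`).
#' @export
select_valid <- function(days, config = reduction_config(), interval = NULL) {
  interval <- interval %||% detect_start_end(days, config)
  if (is.na(interval$start_date)) {
    out <- dplyr::mutate(days,
                         is_valid_day = FALSE,
                         exclusion_reason = "outside_start_end")
    attr(out, "child_included") <- FALSE
    attr(out, "child_exclusion_reason") <- "no_wear_days"
    return(out)
  }
  inside <- days$date >= interval$start_date & days$date <= interval$end_date
  valid <- inside & days$is_valid_day
  reason <- dplyr::case_when(
    !inside ~ "outside_start_end",
    !days$is_wear_day ~ "below_wearday_threshold",
    !valid ~ "below_valid_day_hours",
    TRUE ~ ""
  )
  out <- dplyr::mutate(days, is_valid_day = valid, exclusion_reason = reason)
  included <- sum(valid) >= config$min_valid_days
  attr(out, "child_included") <- included
  attr(out, "child_exclusion_reason") <-
    if (included) "" else "insufficient_valid_days"
  out
}

#' Reduce one child's recording
#'
#' Runs the full cleaning chain on a single series: re-integration to
#' 60 s epochs, spurious flagging, non-wear detection, per-day wear
#' accounting, start/end detection and valid-day/child selection.
#'
#' @param series An [epoch_series()] (any epoch length dividing 60).
#' @param config A [reduction_config()].
#' @return A list with `epochs` (masked 60 s series), `days` (finalized
#'   day records), `interval`, `included` and `exclusion_reason`.
#' @export
reduce_child <- function(series, config = reduction_config()) {
  series60 <- if (epoch_length(series) == 60L) series else {
    suppressMessages(reintegrate(series, 60L))
  }
  series60 <- flag_spurious(series60, config)
  series60 <- detect_nonwear(series60, config)
  days <- registered_time(series60, config)
  interval <- detect_start_end(days, config)
  days <- select_valid(days, config, interval)
  list(epochs = series60,
       days = days,
       interval = interval,
       included = attr(days, "child_included"),
       exclusion_reason = attr(days, "child_exclusion_reason"))
}
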