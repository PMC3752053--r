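#' Intensity cut-points
#'
#' The counts-per-minute thresholds separating sedentary, light and
#' moderate-to-vigorous (MVPA) intensity. Defaults are the child
#' calibration values: sedentary strictly below 100 cpm, MVPA strictly
#' above 2241 cpm; minutes at exactly 100 or 2241 cpm are light.
#'
#' @param sedentary_below Counts/min below which a worn minute is
#'   sedentary (strict).
#' @param mvpa_above Counts/min above which a worn minute is MVPA
#'   (strict).
#' @param label Free-text label carried into outputs.
#' @return A list of class `cut_points`.
#' @export
cut_points <- function(sedentary_below = 100, mvpa_above = 2241,
                       label = "child-calibration") {
  assert_number(sedentary_below, "sedentary_below")
  assert_number(mvpa_above, "mvpa_above")
  if (sedentary_below >= mvpa_above) {
    abort("`sedentary_below` must be strictly less than `mvpa_above`.",
          class = "accel_argument_error")
  }
  structure(list(sedentary_below = sedentary_below, mvpa_above = mvpa_above,
                 label = label),
            class = "cut_points")
}

#' Classify worn minutes by intensity
#'
#' Labels each worn 60 s epoch sedentary (`counts < sedentary_below`),
#' MVPA (`counts > mvpa_above`) or light (otherwise) and tallies minutes
#' per class per calendar date. Per-class minutes sum to the day's
#' registered minutes by construction.
#'
#' @param series A masked [epoch_series()] at 60 s epochs (from
#'   [detect_nonwear()]).
#' @param cuts A [cut_points()] object.
#' @return Tibble with `child_id`, `date`, `sedentary_min`, `light_min`,
#'   `mvpa_min`.
#' @export
classify_intensity <- function(series, cuts = cut_points()) {
  require_minute_epochs(series, "classify_intensity()")
  if (is.null(series$wear)) {
    abort("series has no wear mask; run the reduction first.",
          class = "accel_argument_error")
  }
  worn <- dplyr::filter(series, .data$wear == "WORN")
  secs <- as.numeric(worn$time)
  cls <- dplyr::case_when(
    worn$counts < cuts$sedentary_below ~ "sedentary",
    worn$counts > cuts$mvpa_above ~ "mvpa",
    TRUE ~ "light"
  )
  tal <- tibble::tibble(
    child_id = worn$child_id,
    date = as.Date(secs %/% 86400, origin = "1970-01-01"),
    sedentary = cls == "sedentary",
    light = cls == "light",
    mvpa = cls == "mvpa"
  )
  dplyr::summarise(
    dplyr::group_by(tal, .data$child_id, .data$date),
    sedentary_min = sum(.data$sedentary),
    light_min = sum(.data$light),
    mvpa_min = sum(.data$mvpa),
    .groups = "drop"
  )
}

#' Rescale class minutes to a standard day
#'
#' Registered time varies across days, so per-class minutes are rescaled
#' to a standard day of fixed duration (default 735 min, the conventional
#' mean wear time across reliable days): each class is multiplied by
#' `standard_day / registered_minutes`, so the classes of a valid day sum
#' to exactly `standard_day`. Fractional minutes are kept; use
#' [round_to_standard_day()] when integers are wanted.
#'
#' @param minutes Numeric vector (or column) of class minutes.
#' @param registered_minutes Registered minutes of the same day(s);
#'   must be positive.
#' @param standard_day Standard day length in minutes.
#' @return Rescaled minutes, same length as `minutes`.
#' @examples
#' standardize_day(60, 612.5)  # 72 standardized MVPA minutes
#' @export
standardize_day <- function(minutes, registered_minutes, standard_day = 735) {
  if (any(registered_minutes <= 0)) {
    abort("registered_minutes must be positive to standardize a day.",
          class = "accel_argument_error")
  }
  minutes * standard_day / registered_minutes
}

#' Largest-remainder integer rounding of standardized minutes
#'
#' Rounds a vector of standardized class minutes to integers that sum to
#' `total` exactly, assigning the leftover minutes to the classes with the
#' largest fractional remainders (ties broken by position).
#'
#' @param minutes Non-negative numeric vector summing to `total`.
#' @param total Required integer total (default 735).
#' @return Integer vector summing to `total`.
#' @export
round_to_standard_day <- function(minutes, total = 735) {
  fl <- floor(minutes)
  short <- as.integer(round(total - sum(fl)))
  if (short > 0L) {
    ord <- order(minutes - fl, decreasing = TRUE)
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  as.integer(fl)
}

#' Summarize one child's valid days
#'
#' Aggregates valid wear days into the per-child outcomes: mean cpm
#' pooled over all worn time (total counts over total worn minutes, not a
#' mean of daily means), standardized sedentary hours/day, light and MVPA
#' minutes/day (means of per-day standardized values), plain mean steps
#' per valid day, and the guideline adherence flag (standardized MVPA
#' >= `guideline_min` minutes/day, boundary inclusive).
#'
#' @param days Day tibble holding, for one child, `registered_minutes`,
#'   `counts_sum`, `steps_sum`, `is_valid_day` and the class-minute
#'   columns from [classify_intensity()].
#' @param standard_day Standard day length (minutes).
#' @param guideline_min Guideline threshold on standardized MVPA
#'   (minutes/day).
#' @return One-row tibble: `child_id`, `n_valid_days`, `mean_cpm`,
#'   `sedentary_hours_day`, `light_min_day`, `mvpa_min_day`, `steps_day`,
#'   `meets_guideline`, `season` (season of the first valid day),
#'   `first_valid_date`.
#' @export
summarize_child <- function(days, standard_day = 735, guideline_min = 60) {
  v <- dplyr::filter(days, .data$is_valid_day)
  if (nrow(v) < 2L) {
    abort("summarize_child() requires >= 2 valid days (child should have been excluded upstream).",
          class = "accel_argument_error")
  }
  f <- standard_day / v$registered_minutes
  mvpa_std <- mean(v$mvpa_min * f)
  tibble::tibble(
    child_id = v$child_id[1L],
    n_valid_days = nrow(v),
    mean_cpm = sum(v$counts_sum) / sum(v$registered_minutes),
    sedentary_hours_day = mean(v$sedentary_min * f) / 60,
    light_min_day = mean(v$light_min * f),
    mvpa_min_day = mvpa_std,
    steps_day = mean(v$steps_sum),
    meets_guideline = mvpa_std >= guideline_min,
    season = season_of(min(v$date)),
    first_valid_date = min(v$date)
  )
}

#' Reduce and summarize a cohort of recordings
#'
#' Maps the reduction chain and per-child summary over a set of epoch
#' series and assembles the exclusion flow table. The masked 60 s epochs
#' of every child are retained so that cut-point sensitivity analyses can
#' re-classify without re-reading raw files.
#'
#' @param series_list A list of [epoch_series()] (one per child), e.g.
#'   the `epochs` element of [simulate_cohort()].
#' @param config A [reduction_config()].
#' @param cuts A [cut_points()] object.
#' @param standard_day,guideline_min See [summarize_child()].
#' @return A list of class `cohort_reduction`: `summaries` (one row per
#'   included child), `days` (all day records, all children), `epochs`
#'   (masked 60 s series, included children), `inclusion` (per-child
#'   decision + reason), `flow` (exclusion flow table), `config`, `cuts`.
#' @export
reduce_cohort <- function(series_list, config = reduction_config(),
                          cuts = cut_points(), standard_day = 735,
                          guideline_min = 60) {
  stopifnot(length(series_list) >= 1L)
  per_child <- purrr::map(series_list, function(s) {
    red <- reduce_child(s, config)
    cls <- classify_intensity(red$epochs, cuts)
    days <- dplyr::left_join(red$days, cls, by = c("child_id", "date"))
    days <- dplyr::mutate(days,
                          dplyr::across(c("sedentary_min", "light_min", "mvpa_min"),
                                        ~ tidyr::replace_na(.x, 0)))
    summary <- if (red$included) {
      summarize_child(days, standard_day, guideline_min)
    } else NULL
    list(days = days, epochs = if (red$included) red$epochs else NULL,
         included = red$included, reason = red$exclusion_reason,
         child_id = s$child_id[1L], summary = summary)
  })
  inclusion <- purrr::map_dfr(per_child, function(p) {
    tibble::tibble(child_id = p$child_id, included = p$included,
                   exclusion_reason = p$reason)
  })
  summaries <- purrr::map_dfr(per_child, "summary")
  structure(
    list(summaries = summaries,
         days = purrr::map_dfr(per_child, "days"),
         epochs = purrr::compact(purrr::map(per_child, "epochs")),
         inclusion = inclusion,
         flow = flow_table(inclusion),
         config = config,
         cuts = cuts,
         standard_day = standard_day,
         guideline_min = guideline_min),
    class = "cohort_reduction"
  )
}

#' Exclusion flow table
#'
#' CONSORT-style accounting of a cohort reduction: one row per outcome
#' (`included` plus each exclusion reason) with child counts. Counts
#' always reconcile: they sum to the number of children entering the
#' reduction.
#'
#' @param inclusion Per-child inclusion tibble (from [reduce_cohort()]).
#' @return Tibble with `reason` and `n_children`.
#' @export
flow_table <- function(inclusion) {
  tab <- dplyr::count(
    dplyr::mutate(inclusion,
                  reason = ifelse(.data$included, "included",
                                  .data$exclusion_reason)),
    .data$reason, name = "n_children"
  )
  dplyr::arrange(tab, .data$reason != "included", .data$reason)
}

#' Join child summaries to cohort metadata
#'
#' Produces the cohort analysis table: one row per included child with
#' activity outcomes, sociodemographic covariates and the sampling
#' weight. Weights must be strictly positive and no included child may
#' have missing outcomes.
#'
#' @param summaries Child summaries (from [reduce_cohort()]).
#' @param meta Cohort metadata with `child_id`, covariates and
#'   `sampling_weight`.
#' @return A tibble, one row per included child.
#' @export
cohort_table <- function(summaries, meta) {
  # the measurement season derived from the data (first valid day) takes
  # precedence over any season column carried in the metadata
  dup <- setdiff(intersect(names(meta), names(summaries)), "child_id")
  out <- dplyr::inner_join(summaries,
                           dplyr::select(meta, -dplyr::all_of(dup)),
                           by = "child_id")
  if (any(out$sampling_weight <= 0) || any(is.na(out$sampling_weight))) {
    abort("sampling weights must be strictly positive.",
          class = "accel_data_error")
  }
  key <- c("mean_cpm", "sedentary_hours_day", "mvpa_min_day", "steps_day",
           "meets_guideline")
  if (anyNA(out[key])) {
    abort("included children must not have missing outcome values.",
          class = "accel_data_error")
  }
  out
}

#' Guideline adherence under alternative MVPA cut-points
#'
#' Re-runs intensity classification and child summarization for each MVPA
#' threshold (only `mvpa_above` varies; the wear mask and valid-day
#' selection are threshold-independent) and returns the weighted
#' adherence prevalence by group per threshold. Prevalence is
#' non-increasing in the threshold by construction of MVPA minutes.
#'
#' @param reduction A `cohort_reduction` (from [reduce_cohort()]), which
#'   retains the masked epochs.
#' @param meta Cohort metadata with `sampling_weight` and the grouping
#'   column.
#' @param thresholds Numeric vector of MVPA cut-points (counts/min); each
#'   must exceed the sedentary cut.
#' @param by Name of the grouping column in `meta` (default "gender").
#' @return Tibble with `threshold`, group column, `n`, `prevalence`
#'   (weighted proportion meeting the guideline).
#' @export
cutpoint_sensitivity <- function(reduction, meta, thresholds,
                                 by = "gender") {
  stopifnot(inherits(reduction, "cohort_reduction"))
  if (any(thresholds <= reduction$cuts$sedentary_below)) {
    abort("every MVPA threshold must exceed the sedentary cut-point.",
          class = "accel_argument_error")
  }
  purrr::map_dfr(thresholds, function(thr) {
    cuts <- cut_points(reduction$cuts$sedentary_below, thr,
                       label = sprintf("mvpa>%g", thr))
    summaries <- purrr::map_dfr(reduction$epochs, function(ep) {
      cls <- classify_intensity(ep, cuts)
      days <- dplyr::left_join(
        dplyr::select(
          dplyr::filter(reduction$days, .data$child_id == ep$child_id[1L]),
          -dplyr::any_of(c("sedentary_min", "light_min", "mvpa_min"))
        ),
        cls, by = c("child_id", "date")
      )
      days <- dplyr::mutate(days,
                            dplyr::across(c("sedentary_min", "light_min", "mvpa_min"),
                                          ~ tidyr::replace_na(.x, 0)))
      summarize_child(days, reduction$standard_day, reduction$guideline_min)
    })
    tab <- cohort_table(summaries, meta)
    dplyr::summarise(
      dplyr::group_by(tab, dplyr::across(dplyr::all_of(by))),
      n = dplyr::n(),
      prevalence = weighted.mean(.data$meets_guideline, .data$sampling_weight),
      .groups = "drop"
    ) |>
      dplyr::mutate(threshold = thr, .before = 1L)
  })
}
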