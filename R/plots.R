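#' Plot a child's wear mask by day and time
#'
#' Tile display of the wear mask (worn / non-wear / spurious) over clock
#' time, one row per calendar day — the standard visual check that
#' non-wear detection matches the overnight and within-day gaps.
#'
#' @param series A masked 60 s [epoch_series()] (after
#'   [detect_nonwear()]).
#' @return A ggplot object.
#' @export
plot_wear_mask <- function(series) {
  if (is.null(series$wear)) {
    abort("series has no wear mask; run the reduction first.",
          class = "accel_argument_error")
  }
  secs <- as.numeric(series$time)
  df <- tibble::tibble(
    date = factor(as.Date(secs %/% 86400, origin = "1970-01-01")),
    hour = (secs %% 86400) / 3600,
    wear = series$wear
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$date,
                                   fill = .data$wear)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(WORN = "#2c7fb8",
                                          NONWEAR = "grey85",
                                          SPURIOUS = "#d7301f")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "hour of day", y = NULL, fill = NULL,
                  title = series$child_id[1L]) +
    ggplot2::theme_minimal()
}

#' Plot adherence prevalence against the MVPA cut-point
#'
#' @param sensitivity Output of [cutpoint_sensitivity()].
#' @return A ggplot object.
#' @export
plot_cutpoint_sensitivity <- function(sensitivity) {
  grp <- setdiff(names(sensitivity), c("threshold", "n", "prevalence"))[1L]
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = .data$threshold,
                               y = 100 * .data$prevalence,
                               colour = .data[[grp]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "MVPA cut-point (counts/min)",
                  y = "% meeting guideline", colour = grp) +
    ggplot2::theme_minimal()
}

#' Plot season-adjusted group medians with intervals
#'
#' @param quantiles Output of [season_adjusted_quantiles()] (long form);
#'   the median rows are drawn as points, the quartiles as a range.
#' @return A ggplot object.
#' @export
plot_group_quantiles <- function(quantiles) {
  wide <- tidyr::pivot_wider(quantiles[c("group", "prob", "estimate")],
                             names_from = "prob", values_from = "estimate",
                             names_prefix = "p")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$group, y = .data$p0.5)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p0.25,
                                          ymax = .data$p0.75)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "season-adjusted median (IQR)") +
    ggplot2::theme_minimal()
}
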