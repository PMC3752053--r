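#' Astronomical season of a date
#'
#' Seasons follow the astronomical convention: spring 21 March--20 June,
#' summer 21 June--20 September, autumn 21 September--20 December, winter
#' 21 December--20 March. Boundary dates belong to the season whose
#' interval starts on them.
#'
#' @param date A `Date` vector (or something coercible).
#' @return A factor with levels spring, summer, autumn, winter.
#' @examples
#' season_of(as.Date(c("2008-03-21", "2008-12-20", "2008-12-21")))
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  out <- dplyr::case_when(
    md >= 321L & md <= 620L ~ "spring",
    md >= 621L & md <= 920L ~ "summer",
    md >= 921L & md <= 1220L ~ "autumn",
    TRUE ~ "winter"
  )
  factor(out, levels = season_levels())
}

season_levels <- function() c("spring", "summer", "autumn", "winter")

#' Weighted quantiles (inverse-CDF type)
#'
#' The weighted quantile at probability `p` is the smallest observed
#' value whose cumulative normalized weight reaches `p`. With equal
#' weights this is the ordinary type-1 sample quantile, the right
#' estimator for the skewed activity outcomes summarized by medians and
#' IQRs.
#'
#' @param x Numeric values.
#' @param w Positive weights (default equal).
#' @param probs Probabilities in (0, 1); default quartiles.
#' @return Named numeric vector of quantile estimates.
#' @examples
#' weighted_quantile(c(1, 2), w = c(3, 1), probs = 0.5)  # 1
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.25, 0.5, 0.75)) {
  if (length(x) == 0L) {
    abort("cannot compute quantiles of an empty sample.",
          class = "accel_argument_error")
  }
  w <- w %||% rep(1, length(x))
  if (length(w) != length(x) || any(is.na(w)) || any(w <= 0)) {
    abort("weights must be positive and match `x` in length.",
          class = "accel_argument_error")
  }
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    x[ord][which(cw >= p - 1e-12)[1L]]
  }, numeric(1)) |> setNames(paste0("p", probs * 100))
}

#' Season-standardized group quantiles
#'
#' Group medians and quartiles adjusted for season of measurement by
#' direct standardization: within each group, children are reweighted so
#' that the group's season distribution matches the cohort-wide
#' (weighted) season distribution, and weighted quantiles are computed
#' from the reweighted sample. With a single season present this reduces
#' to [weighted_quantile()]. Optional bootstrap (resampling children
#' within group) supplies standard errors and percentile intervals.
#'
#' @param data A cohort table (one row per child).
#' @param outcome Bare column name of the outcome.
#' @param by Bare column name of the grouping factor, or omitted for the
#'   whole cohort.
#' @param weights Bare column name of the sampling weights (default
#'   `sampling_weight`).
#' @param season Bare column name of the season factor (default
#'   `season`).
#' @param probs Probabilities (default quartiles).
#' @param incomplete How to treat a group missing a season present in
#'   the cohort: `"renormalize"` (default) standardizes over the seasons
#'   the group has, recording them in `missing_seasons`; `"suppress"`
#'   returns `NA` estimates for that group.
#' @param n_boot Bootstrap replicates (0 = no uncertainty estimates).
#' @param seed Seed for the bootstrap.
#' @return Tibble with one row per group x probability: `group`, `prob`,
#'   `estimate`, and with bootstrap also `se`, `conf_low`, `conf_high`.
#' @export
season_adjusted_quantiles <- function(data, outcome, by = NULL,
                                      weights = sampling_weight,
                                      season = season,
                                      probs = c(0.25, 0.5, 0.75),
                                      incomplete = c("renormalize", "suppress"),
                                      n_boot = 0, seed = NULL) {
  incomplete <- match.arg(incomplete)
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ outcome }}),
    w = dplyr::pull(data, {{ weights }}),
    s = as.character(dplyr::pull(data, {{ season }}))
  )
  by_quo <- rlang::enquo(by)
  df$g <- if (rlang::quo_is_null(by_quo)) "all" else {
    as.character(dplyr::pull(data, {{ by }}))
  }
  season_w <- tapply(df$w, df$s, sum)
  season_w <- season_w / sum(season_w)  # cohort-wide season distribution

  estimate_group <- function(d) {
    present <- unique(d$s)
    missing <- setdiff(names(season_w), present)
    if (length(missing) > 0L && incomplete == "suppress") {
      return(list(q = setNames(rep(NA_real_, length(probs)),
                               paste0("p", probs * 100)),
                  missing = missing))
    }
    pi_target <- season_w[present] / sum(season_w[present])
    pi_group <- tapply(d$w, d$s, sum)[present]
    pi_group <- pi_group / sum(pi_group)
    w_adj <- d$w * as.numeric(pi_target[d$s] / pi_group[d$s])
    list(q = weighted_quantile(d$y, w_adj, probs), missing = missing)
  }

  groups <- split(df, df$g)
  point <- purrr::imap_dfr(groups, function(d, gname) {
    est <- estimate_group(d)
    tibble::tibble(group = gname, prob = probs, estimate = as.numeric(est$q),
                   n = nrow(d),
                   missing_seasons = paste(est$missing, collapse = ";"))
  })
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      purrr::map(groups, function(d) {
        replicate(n_boot, {
          idx <- sample.int(nrow(d), replace = TRUE)
          as.numeric(estimate_group(d[idx, , drop = FALSE])$q)
        })
      })
    })
    unc <- purrr::imap_dfr(boots, function(b, gname) {
      b <- matrix(b, nrow = length(probs))
      tibble::tibble(group = gname, prob = probs,
                     se = apply(b, 1L, sd, na.rm = TRUE),
                     conf_low = apply(b, 1L, quantile, 0.025, na.rm = TRUE),
                     conf_high = apply(b, 1L, quantile, 0.975, na.rm = TRUE))
    })
    point <- dplyr::left_join(point, unc, by = c("group", "prob"))
  }
  point
}
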