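#' Synthetic cohort simulation configuration
#'
#' Parameters of the seeded epoch-level cohort generator. The generator
#' emulates the structure a 7-day waist-worn accelerometer protocol in
#' 7--8-year-olds produces: 15 s count/step epochs over multiple days,
#' waking-hours wear with occasional within-day non-wear bouts, exact
#' zeros when the monitor is off, right-skewed count distributions with
#' a three-state (sedentary/light/MVPA) bout process, counts-coupled
#' steps, rare spurious count spikes, and gender/ethnicity/season/region
#' multiplicative effects on MVPA occupancy. Alongside the epoch data it
#' emits the latent ground truth (per-day wear and class minutes, per
#' child the true occupancy and adherence), so every reduction rule can
#' be checked against what was planted.
#'
#' Intensity calibration targets the published cohort summaries for this
#' age group (overall ~595 cpm, ~60 MVPA min/day, ~6.4 sedentary h/day,
#' ~10 200 steps/day, boys/girls adherence ~63%/38%); see the methods
#' vignette for the derivation of each default.
#'
#' @param n_children Number of children.
#' @param days_per_child Protocol days of full wear (default 7).
#' @param epoch_seconds Recording epoch (15 or 60).
#' @param seed Master seed; fully determines the output.
#' @param wear List: `start_mean_hour`, `start_sd_hour`, `end_mean_hour`,
#'   `end_sd_hour` (daily wear-on/off clock times), `nonwear_rate`
#'   (bouts/day), `nonwear_min_minutes`, `nonwear_extra_meanlog`,
#'   `nonwear_extra_sdlog` (bout length = min + lognormal extra),
#'   `transit_days` (add one low-wear postal day before and after the
#'   protocol), `soft_nonwear_rate` (probability a non-wear minute
#'   carries a small nonzero artefact; 0 by default).
#' @param intensity List: `sedentary_occupancy` (share of wear),
#'   `mvpa_base_occupancy`, `dwell_minutes` (mean bout lengths per
#'   state), `sedentary_mean_cpm`, `light_meanlog`, `light_sdlog`,
#'   `mvpa_meanlog`, `mvpa_sdlog`, `child_sdlog` (between-child spread of
#'   MVPA occupancy), `boundary_guard` (keep counts >= 2 cpm away from
#'   the 100/2241 cut-points so classification is unambiguous).
#' @param steps List: `per_count`, `noise_sdlog`, `max_per_minute`.
#' @param spurious List: `rate` (per worn minute), `min_cpm`, `max_cpm`.
#' @param effects List of named multiplier vectors on MVPA occupancy:
#'   `gender`, `ethnicity`, `season`, `country`, `england_region`.
#' @param weight_sdlog Lognormal sd of the sampling weights.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_children = 200,
                              days_per_child = 7,
                              epoch_seconds = 15,
                              seed = 1L,
                              wear = list(),
                              intensity = list(),
                              steps = list(),
                              spurious = list(),
                              effects = list(),
                              weight_sdlog = 0.3) {
  wear_def <- list(start_mean_hour = 7.75, start_sd_hour = 0.4,
                   end_mean_hour = 20.5, end_sd_hour = 0.4,
                   nonwear_rate = 0.7, nonwear_min_minutes = 25,
                   nonwear_extra_meanlog = log(20), nonwear_extra_sdlog = 0.5,
                   transit_days = TRUE, soft_nonwear_rate = 0)
  intensity_def <- list(sedentary_occupancy = 0.522,
                        mvpa_base_occupancy = 60.1 / 735,
                        dwell_minutes = c(sedentary = 5, light = 3, mvpa = 2),
                        sedentary_mean_cpm = 25,
                        light_meanlog = log(620), light_sdlog = 0.65,
                        mvpa_meanlog = log(3100), mvpa_sdlog = 0.35,
                        child_sdlog = 0.355,
                        boundary_guard = TRUE)
  steps_def <- list(per_count = 0.024, noise_sdlog = 0.12,
                    max_per_minute = 220)
  spurious_def <- list(rate = 2e-4, min_cpm = 12000, max_cpm = 20000)
  effects_def <- list(
    gender = c(male = 1.11, female = 0.90),
    ethnicity = c(White = 1.00, Mixed = 1.035, Indian = 0.875,
                  Pakistani = 0.968, Bangladeshi = 0.880, Black = 1.050,
                  Other = 0.968),
    season = c(spring = 1.02, summer = 1.10, autumn = 0.95, winter = 0.88),
    country = c(England = 1.00, Wales = 1.01, Scotland = 1.02,
                `Northern Ireland` = 0.93),
    england_region = c("North East" = 1.00, "North West" = 1.06,
                       "Yorkshire and the Humber" = 1.00,
                       "East Midlands" = 0.94, "West Midlands" = 0.94,
                       "East of England" = 1.00, "London" = 1.00,
                       "South East" = 1.00, "South West" = 1.00)
  )
  cfg <- list(
    n_children = as.integer(n_children),
    days_per_child = as.integer(days_per_child),
    epoch_seconds = as.integer(epoch_seconds),
    seed = as.integer(seed),
    wear = utils::modifyList(wear_def, wear),
    intensity = utils::modifyList(intensity_def, intensity),
    steps = utils::modifyList(steps_def, steps),
    spurious = utils::modifyList(spurious_def, spurious),
    effects = utils::modifyList(effects_def, effects),
    weight_sdlog = weight_sdlog
  )
  if (!cfg$epoch_seconds %in% c(15L, 60L)) {
    abort("`epoch_seconds` must be 15 or 60.", class = "accel_argument_error")
  }
  if (cfg$n_children < 1L || cfg$days_per_child < 1L) {
    abort("`n_children` and `days_per_child` must be >= 1.",
          class = "accel_argument_error")
  }
  structure(cfg, class = "simulation_config")
}

# Truncated lognormal draws via inverse-CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

# Split integer per-minute totals into 4 quarter-minute epochs,
# conserving the total exactly (sequential binomial thinning).
split_minute <- function(x) {
  x <- as.integer(round(x))
  a <- rbinom(length(x), x, 1 / 4)
  b <- rbinom(length(x), x - a, 1 / 3)
  c3 <- rbinom(length(x), x - a - b, 1 / 2)
  rbind(a, b, c3, x - a - b - c3)
}

#' Draw sociodemographic metadata for a synthetic cohort
#'
#' Gender, 7-group ethnicity, maternal occupation class, lone-parent and
#' other-children indicators, country/English region, measurement start
#' date (uniform over a May 2008 -- August 2009 fieldwork window) and
#' lognormal sampling weights. Category frequencies follow the published
#' cohort composition.
#'
#' @param cfg A [simulation_config()].
#' @return Tibble, one row per child.
#' @export
simulate_metadata <- function(cfg) {
  n <- cfg$n_children
  with_seed(derive_seed(cfg$seed, 0L), {
    ethnicity <- sample(names(cfg$effects$ethnicity), n, replace = TRUE,
                        prob = c(0.8789, 0.0259, 0.0214, 0.0272, 0.0108,
                                 0.0219, 0.0139))
    country <- sample(names(cfg$effects$country), n, replace = TRUE,
                      prob = c(0.647, 0.138, 0.117, 0.098))
    region <- ifelse(
      country == "England",
      sample(names(cfg$effects$england_region), n, replace = TRUE,
             prob = c(0.05, 0.13, 0.10, 0.09, 0.11, 0.11, 0.15, 0.16, 0.10)),
      country
    )
    occupation <- sample(c("managerial_professional", "intermediate",
                           "small_employer", "lower_supervisory",
                           "semiroutine_routine", "never_worked"),
                         n, replace = TRUE,
                         prob = c(0.350, 0.192, 0.071, 0.046, 0.298, 0.043))
    start <- as.Date("2008-05-12") +
      sample.int(as.integer(as.Date("2009-08-09") - as.Date("2008-05-12")),
                 n, replace = TRUE)
    tibble::tibble(
      child_id = sprintf("child_%04d", seq_len(n)),
      gender = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(0.489, 0.511)),
      ethnicity = ethnicity,
      occupation = occupation,
      lone_parent = runif(n) < 0.148,
      other_children = runif(n) < 0.888,
      country = country,
      region = region,
      start_date = start,
      season = season_of(start),
      sampling_weight = rlnorm(n, 0, cfg$weight_sdlog)
    )
  })
}

# True MVPA occupancy for one child given covariates.
child_theta <- function(cfg, covs, noise) {
  ef <- cfg$effects
  region_mult <- if (covs$country == "England") {
    unname(ef$england_region[covs$region])
  } else 1
  th <- cfg$intensity$mvpa_base_occupancy *
    unname(ef$gender[covs$gender]) *
    unname(ef$ethnicity[covs$ethnicity]) *
    unname(ef$season[as.character(covs$season)]) *
    unname(ef$country[covs$country]) * region_mult * exp(noise)
  min(max(th, 0), 0.40)
}

#' Simulate one child's epoch recording with ground truth
#'
#' Draws the child's true MVPA occupancy from the configured effect
#' structure, simulates per-day wear windows, planted non-wear bouts, a
#' bout-level three-state intensity process with state-specific count
#' distributions, counts-coupled steps and spurious spikes, and returns
#' the epoch series together with the per-day latent truth. Non-wear
#' (and un-worn) minutes are exact zeros. The draw is fully determined
#' by `cfg$seed` and `child_index`.
#'
#' @param cfg A [simulation_config()].
#' @param child_index 1-based child index (seeds the child's stream).
#' @param covariates Optional one-row metadata tibble (from
#'   [simulate_metadata()]); a neutral default child is used if omitted.
#' @return List: `series` (an [epoch_series()]), `truth_days` (per-day
#'   latent quantities), `theta` (true MVPA occupancy).
#' @export
simulate_child <- function(cfg, child_index, covariates = NULL) {
  covs <- covariates %||% tibble::tibble(
    child_id = sprintf("child_%04d", child_index),
    gender = "female", ethnicity = "White", country = "England",
    region = "London", start_date = as.Date("2008-06-02"),
    season = season_of(as.Date("2008-06-02"))
  )
  with_seed(derive_seed(cfg$seed, child_index), {
    theta <- child_theta(cfg, covs, rnorm(1, 0, cfg$intensity$child_sdlog))
    sim <- simulate_child_minutes(cfg, covs, theta)
    series <- minutes_to_series(cfg, covs, sim)
    list(series = series, truth_days = sim$truth_days, theta = theta)
  })
}

# Minute-grid simulation for all days of one child. Returns per-minute
# vectors (counts, steps) and the per-day truth table.
simulate_child_minutes <- function(cfg, covs, theta) {
  wearp <- cfg$wear
  intp <- cfg$intensity
  n_protocol <- cfg$days_per_child
  transit <- isTRUE(wearp$transit_days)
  n_days <- n_protocol + if (transit) 2L else 0L
  day_dates <- covs$start_date + seq_len(n_days) - 1L

  occ_sed <- intp$sedentary_occupancy
  occ_mvpa <- theta
  occ_light <- max(1 - occ_sed - occ_mvpa, 0.01)
  occ <- c(occ_sed, occ_light, occ_mvpa) / sum(occ_sed, occ_light, occ_mvpa)
  dwell <- intp$dwell_minutes
  bout_prob <- occ / dwell
  bout_prob <- bout_prob / sum(bout_prob)

  counts <- numeric(n_days * 1440L)
  steps <- numeric(n_days * 1440L)
  state <- integer(n_days * 1440L)    # 0 off, 1 sed, 2 light, 3 mvpa
  spur <- logical(n_days * 1440L)

  truth_days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    off <- (d - 1L) * 1440L
    is_transit <- transit && (d == 1L || d == n_days)
    if (is_transit) {
      # postal-transit day: brief handling only (< 150 waking minutes)
      wstart <- if (d == 1L) 16L * 60L else 8L * 60L
      wend <- wstart + 60L
    } else {
      wstart <- round(rnorm(1, wearp$start_mean_hour * 60,
                            wearp$start_sd_hour * 60))
      wend <- round(rnorm(1, wearp$end_mean_hour * 60,
                          wearp$end_sd_hour * 60))
      wstart <- min(max(wstart, 0L), 720L)
      wend <- min(max(wend, wstart + 120L), 1440L)
    }
    span <- seq.int(wstart + 1L, wend)    # 1-based minute indices of the day
    worn <- rep(TRUE, length(span))
    n_bouts <- if (is_transit) 0L else rpois(1, wearp$nonwear_rate)
    planted <- 0L
    if (n_bouts > 0L) {
      for (b in seq_len(n_bouts)) {
        dur <- round(wearp$nonwear_min_minutes +
                       rlnorm(1, wearp$nonwear_extra_meanlog,
                              wearp$nonwear_extra_sdlog))
        if (length(span) > dur + 4L) {
          s0 <- sample.int(length(span) - dur - 2L, 1L) + 1L
          worn[seq.int(s0, s0 + dur - 1L)] <- FALSE
        }
      }
      planted <- sum(!worn)
    }

    # bout-level three-state process over the worn minutes
    n_worn <- sum(worn)
    if (n_worn > 0L) {
      n_draw <- max(8L, ceiling(2.5 * n_worn / min(dwell)))
      st <- sample.int(3L, n_draw, replace = TRUE, prob = bout_prob)
      len <- 1L + rpois(n_draw, dwell[st] - 1)
      seq_states <- rep.int(st, len)
      while (length(seq_states) < n_worn) {  # vanishingly rare shortfall
        st2 <- sample.int(3L, n_draw, replace = TRUE, prob = bout_prob)
        len2 <- 1L + rpois(n_draw, dwell[st2] - 1)
        seq_states <- c(seq_states, rep.int(st2, len2))
      }
      seq_states <- seq_states[seq_len(n_worn)]
      day_state <- integer(1440L)
      day_state[span[worn]] <- seq_states

      m_counts <- numeric(n_worn)
      i_sed <- seq_states == 1L
      i_light <- seq_states == 2L
      i_mvpa <- seq_states == 3L
      if (any(i_sed)) {
        cs <- 1 + rpois(sum(i_sed), intp$sedentary_mean_cpm - 1)
        m_counts[i_sed] <- pmin(cs, if (intp$boundary_guard) 98 else 99)
      }
      if (any(i_light)) {
        lo <- if (intp$boundary_guard) 102 else 100
        hi <- if (intp$boundary_guard) 2239 else 2241
        m_counts[i_light] <- round(rlnorm_trunc(sum(i_light),
                                                intp$light_meanlog,
                                                intp$light_sdlog, lo, hi))
      }
      if (any(i_mvpa)) {
        lo <- if (intp$boundary_guard) 2243 else 2242
        m_counts[i_mvpa] <- round(rlnorm_trunc(sum(i_mvpa),
                                               intp$mvpa_meanlog,
                                               intp$mvpa_sdlog, lo, 11000))
      }
      sp <- runif(n_worn) < cfg$spurious$rate
      if (any(sp)) {
        m_counts[sp] <- round(runif(sum(sp), cfg$spurious$min_cpm,
                                    cfg$spurious$max_cpm))
      }
      m_steps <- pmin(round(m_counts * cfg$steps$per_count *
                              rlnorm(n_worn, 0, cfg$steps$noise_sdlog)),
                      cfg$steps$max_per_minute)
      idx <- off + span[worn]
      counts[idx] <- m_counts
      steps[idx] <- m_steps
      state[idx] <- seq_states
      spur[idx] <- sp
    }
    if (wearp$soft_nonwear_rate > 0 && any(!worn)) {
      nw_idx <- off + span[!worn]
      artefact <- runif(length(nw_idx)) < wearp$soft_nonwear_rate
      counts[nw_idx[artefact]] <- round(runif(sum(artefact), 1, 50))
    }

    day_minute <- seq_len(1440L)
    waking <- day_minute >= 7L * 60L + 1L & day_minute <= 22L * 60L
    w_idx <- span[worn]
    keep <- !spur[off + w_idx]
    st_day <- state[off + w_idx][keep]
    truth_days[[d]] <- tibble::tibble(
      child_id = covs$child_id,
      date = day_dates[d],
      wear_min = sum(keep),
      waking_wear_min = sum(waking[w_idx][keep]),
      sedentary_min = sum(st_day == 1L),
      light_min = sum(st_day == 2L),
      mvpa_min = sum(st_day == 3L),
      nonwear_bout_min = planted,
      n_spurious = sum(!keep),
      is_transit = is_transit
    )
  }

  if (cfg$epoch_seconds == 15L) {
    ep_counts <- as.numeric(split_minute(counts))
    ep_steps <- as.numeric(split_minute(steps))
  } else {
    ep_counts <- counts
    ep_steps <- steps
  }
  list(counts = ep_counts, steps = ep_steps,
       truth_days = dplyr::bind_rows(truth_days))
}

minutes_to_series <- function(cfg, covs, sim) {
  start <- as.POSIXct(paste(covs$start_date, "00:00:00"), tz = "UTC")
  n <- length(sim$counts)
  out <- tibble::tibble(
    child_id = covs$child_id,
    time = start + (seq_len(n) - 1L) * as.numeric(cfg$epoch_seconds),
    counts = sim$counts,
    steps = sim$steps
  )
  new_epoch_series(out, cfg$epoch_seconds)
}

#' Simulate a full synthetic cohort
#'
#' Draws metadata, simulates every child's epoch recording, and derives
#' the ground-truth child summaries by applying the stated validity and
#' standardization rules to the latent per-day truth (>= 150 waking
#' minutes delimiting the wear period, >= 600 registered minutes for a
#' valid day, >= 2 valid days for inclusion, 735-min standard day,
#' >= 60 standardized MVPA min/day for adherence).
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional directory; when given, epoch files (plain
#'   dialect), `meta.csv` and `truth.csv` are written there.
#' @return List of class `synthetic_cohort`: `epochs` (list of
#'   [epoch_series()]), `meta`, `truth_days`, `truth_children`, `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config(), dir = NULL) {
  meta <- simulate_metadata(cfg)
  sims <- purrr::map(seq_len(cfg$n_children), function(i) {
    simulate_child(cfg, i, meta[i, ])
  })
  truth_days <- purrr::map_dfr(sims, "truth_days")
  theta <- purrr::map_dbl(sims, "theta")
  truth_children <- truth_child_summaries(truth_days, theta, meta)
  out <- structure(
    list(epochs = purrr::map(sims, "series"),
         meta = meta,
         truth_days = truth_days,
         truth_children = truth_children,
         config = cfg),
    class = "synthetic_cohort"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk(out$epochs, function(s) {
      write_epoch_file(s, file.path(dir, paste0(s$child_id[1L], ".csv")))
    })
    write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
    write.csv(truth_children, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out
}

# Apply the validity + standardization rules to the latent truth.
truth_child_summaries <- function(truth_days, theta, meta,
                                  standard_day = 735, guideline_min = 60,
                                  wearday_min = 150, validday_min = 600,
                                  min_valid_days = 2) {
  per_child <- split(truth_days, truth_days$child_id)
  tab <- purrr::imap_dfr(per_child, function(d, id) {
    wearish <- d$waking_wear_min >= wearday_min
    if (!any(wearish)) {
      return(tibble::tibble(child_id = id, included = FALSE,
                            n_valid_days = 0L,
                            true_mvpa_min_day = NA_real_,
                            true_sedentary_hours_day = NA_real_,
                            true_steps_day = NA_real_,
                            true_mean_cpm = NA_real_,
                            true_meets_guideline = NA))
    }
    lo <- min(d$date[wearish]); hi <- max(d$date[wearish])
    valid <- d$date >= lo & d$date <= hi & wearish & d$wear_min >= validday_min
    v <- d[valid, , drop = FALSE]
    if (nrow(v) < min_valid_days) {
      return(tibble::tibble(child_id = id, included = FALSE,
                            n_valid_days = nrow(v),
                            true_mvpa_min_day = NA_real_,
                            true_sedentary_hours_day = NA_real_,
                            true_steps_day = NA_real_,
                            true_mean_cpm = NA_real_,
                            true_meets_guideline = NA))
    }
    f <- standard_day / v$wear_min
    mv <- mean(v$mvpa_min * f)
    tibble::tibble(child_id = id, included = TRUE, n_valid_days = nrow(v),
                   true_mvpa_min_day = mv,
                   true_sedentary_hours_day = mean(v$sedentary_min * f) / 60,
                   true_steps_day = NA_real_,
                   true_mean_cpm = NA_real_,
                   true_meets_guideline = mv >= guideline_min)
  })
  tab <- dplyr::left_join(
    tab,
    tibble::tibble(child_id = meta$child_id, theta = theta,
                   expected_mvpa_min_day = theta * standard_day),
    by = "child_id"
  )
  dplyr::arrange(tab, .data$child_id)
}
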