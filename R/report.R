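#' Cohort summary report by sociodemographic group
#'
#' Builds the standard cohort description table: for each grouping
#' factor and level, the number of children, season-adjusted weighted
#' median and quartiles of each activity outcome, the covariate-adjusted
#' prevalence (with bootstrap SE) of meeting the activity guideline, and
#' letter superindices marking pairs of levels that differ significantly
#' after Benjamini-Hochberg correction at `q`.
#'
#' @param cohort A cohort table ([cohort_table()]): one row per included
#'   child with outcomes, covariates, `season` and `sampling_weight`.
#' @param by Character vector of grouping factor columns.
#' @param outcomes Character vector of outcome columns to summarize with
#'   medians/IQRs.
#' @param adjust_for Covariates for prevalence adjustment; for each
#'   factor in `by` the model adjusts for the other listed covariates
#'   plus season.
#' @param q FDR level for pairwise annotation.
#' @param n_boot Bootstrap replicates for SEs and pairwise p-values.
#' @param seed Seed.
#' @param pairwise Compute pairwise significance markers (slowest part).
#' @return Object of class `cohort_report`: `groups` (the shaped table),
#'   `pairwise` (per factor/outcome test details), `overall` (whole
#'   cohort row), `q`.
#' @export
cohort_report <- function(cohort,
                          by = c("gender", "country"),
                          outcomes = c("mean_cpm", "sedentary_hours_day",
                                       "mvpa_min_day", "steps_day"),
                          adjust_for = by,
                          q = 0.05, n_boot = 199, seed = NULL,
                          pairwise = TRUE) {
  overall <- purrr::map_dfr(outcomes, function(oc) {
    qs <- season_adjusted_quantiles(cohort, oc)
    tibble::tibble(outcome = oc,
                   q25 = qs$estimate[qs$prob == 0.25],
                   median = qs$estimate[qs$prob == 0.5],
                   q75 = qs$estimate[qs$prob == 0.75])
  })
  overall_prev <- weighted.mean(cohort$meets_guideline,
                                cohort$sampling_weight)

  pairwise_detail <- list()
  groups <- purrr::map_dfr(by, function(fac) {
    base <- dplyr::count(cohort, level = as.character(.data[[fac]]),
                         name = "n")
    for (oc in outcomes) {
      qs <- season_adjusted_quantiles(cohort, oc, by = fac)
      wide <- tidyr::pivot_wider(
        dplyr::mutate(qs, prob = paste0("q", .data$prob * 100)),
        id_cols = "group", names_from = "prob", values_from = "estimate"
      )
      names(wide) <- c("level", paste0(oc, c("_q25", "_median", "_q75")))
      base <- dplyr::left_join(base, wide, by = "level")
      if (pairwise && dplyr::n_distinct(base$level) > 1L) {
        pw <- pairwise_group_tests(cohort, oc, fac,
                                   type = "median", n_boot = n_boot,
                                   q = q, seed = seed)
        pairwise_detail[[paste(fac, oc, sep = ".")]] <<- pw
        mk <- markers_by_level(pw, base$level)
        base[[paste0(oc, "_marker")]] <- mk[base$level]
      }
    }
    covs <- setdiff(unique(c(adjust_for, "season")), fac)
    prev <- tryCatch(
      adjusted_prevalence(cohort, "meets_guideline",
                          exposure = fac, covariates = covs,
                          n_boot = n_boot, seed = seed),
      accel_estimation_error = function(e) {
        warn(sprintf("adjusted prevalence for '%s' not estimable (%s); reporting NA.",
                     fac, conditionMessage(e)))
        NULL
      }
    )
    pt <- if (is.null(prev)) {
      tibble::tibble(level = unique(base$level), prevalence = NA_real_,
                     se = NA_real_)
    } else tidy(prev)
    base <- dplyr::left_join(
      base,
      dplyr::transmute(pt, level = .data$level,
                       prevalence_pct = 100 * .data$prevalence,
                       prevalence_se = .data$se),
      by = "level"
    )
    if (pairwise && dplyr::n_distinct(base$level) > 1L) {
      pwp <- pairwise_group_tests(cohort, "meets_guideline",
                                  fac, type = "prevalence",
                                  n_boot = n_boot, q = q, seed = seed)
      pairwise_detail[[paste(fac, "prevalence", sep = ".")]] <<- pwp
      mk <- markers_by_level(pwp, base$level)
      base$prevalence_marker <- mk[base$level]
    }
    dplyr::mutate(base, factor = fac, .before = 1L)
  })
  structure(
    list(groups = groups,
         overall = dplyr::mutate(overall,
                                 prevalence_pct = 100 * overall_prev),
         pairwise = pairwise_detail,
         n = nrow(cohort), q = q, n_boot = n_boot),
    class = "cohort_report"
  )
}

# Letter superscripts per level: a level collects the letters of the
# significant pairs it belongs to.
markers_by_level <- function(pairs_tbl, levels) {
  out <- setNames(rep("", length(levels)), levels)
  sig <- pairs_tbl[pairs_tbl$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    for (lv in c(sig$level_a[i], sig$level_b[i])) {
      out[lv] <- paste0(out[lv], sig$marker[i])
    }
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort activity report (n = %d children; BH-adjusted pairwise markers at q = %g)\n",
              x$n, x$q))
  print(x$groups, n = Inf)
  invisible(x)
}

#' Simulate a cohort summary table from a planted inference model
#'
#' Generates child-level summary rows directly (no epoch simulation)
#' from a stated logistic adherence model and multiplicative
#' gender/season effects on MVPA minutes, for testing the inference
#' layer against known truth. Adherence follows
#' `logit P = intercept + gender_male + season_effect`; MVPA min/day is
#' lognormal around `mvpa_median` times the gender and season
#' multipliers.
#'
#' Default coefficients place girls-in-spring adherence at
#' `plogis(-0.498) = 0.378` and boys at `plogis(0.546) = 0.633`, the
#' published gender-specific prevalences.
#'
#' @param n Children.
#' @param coef List: `intercept`, `male`, `season` (named vector of 4,
#'   spring = 0 reference).
#' @param mvpa List: `median` (girls/spring), `gender_mult`,
#'   `season_mult` (named vectors), `sdlog`.
#' @param weight_sdlog Sampling-weight lognormal sd.
#' @param seed Seed.
#' @return List of class `planted_cohort`: `data` (tibble with `gender`,
#'   `season`, `sampling_weight`, `meets_guideline`, `mvpa_min_day`),
#'   `coef`, `mvpa`, plus `true_prevalence()`-style truth in
#'   `truth` (marginally standardized level prevalences implied by the
#'   model and the realized covariate distribution).
#' @export
simulate_cohort_table <- function(n = 500,
                                  coef = list(
                                    intercept = -0.498, male = 1.044,
                                    season = c(spring = 0, summer = 0.3,
                                               autumn = -0.15, winter = -0.35)),
                                  mvpa = list(
                                    median = 60.1,
                                    gender_mult = c(male = 1.116, female = 0.905),
                                    season_mult = c(spring = 1.02, summer = 1.10,
                                                    autumn = 0.95, winter = 0.88),
                                    sdlog = 0.355),
                                  weight_sdlog = 0.3,
                                  seed = 1L) {
  with_seed(seed, {
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.489, 0.511))
    season <- factor(sample(season_levels(), n, replace = TRUE),
                     levels = season_levels())
    eta <- coef$intercept + coef$male * (gender == "male") +
      coef$season[as.character(season)]
    p <- stats::plogis(eta)
    data <- tibble::tibble(
      child_id = sprintf("pc_%04d", seq_len(n)),
      gender = gender,
      season = season,
      sampling_weight = rlnorm(n, 0, weight_sdlog),
      meets_guideline = runif(n) < p,
      mvpa_min_day = mvpa$median * mvpa$gender_mult[gender] *
        mvpa$season_mult[as.character(season)] * rlnorm(n, 0, mvpa$sdlog)
    )
    # marginal-standardization truth for gender, over the realized
    # covariate (season) distribution
    truth <- purrr::map_dfr(c("male", "female"), function(g) {
      eta_g <- coef$intercept + coef$male * (g == "male") +
        coef$season[as.character(season)]
      tibble::tibble(level = g,
                     true_prevalence = mean(stats::plogis(eta_g)))
    })
    structure(list(data = data, coef = coef, mvpa = mvpa, truth = truth),
              class = "planted_cohort")
  })
}
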