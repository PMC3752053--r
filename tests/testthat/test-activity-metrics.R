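test_that("intensity boundaries: 100 and 2241 cpm are light", {
  day <- worn_day(c(50, 100, 2241, 2242))
  cls <- classify_intensity(day)
  expect_equal(cls$sedentary_min, 1)
  expect_equal(cls$light_min, 2)
  expect_equal(cls$mvpa_min, 1)

  allzero <- worn_day(rep(0, 600))
  # zeros become non-wear when runs are long; force a short-zero day
  short <- worn_day(rep(c(0, 99), 300))
  cls2 <- classify_intensity(short)
  expect_equal(cls2$sedentary_min, 600)
})

test_that("class minutes sum to registered minutes and match a brute-force scan", {
  set.seed(21)
  for (i in 1:50) {
    counts <- sample(c(0, 40, 99, 100, 101, 1500, 2241, 2242, 5000, 12000),
                     400, replace = TRUE)
    s <- worn_day(counts)
    cls <- classify_intensity(s)
    d <- registered_time(s)
    expect_equal(cls$sedentary_min + cls$light_min + cls$mvpa_min,
                 sum(d$registered_minutes))
    worn <- s$counts[s$wear == "WORN"]
    expect_equal(cls$sedentary_min, sum(worn < 100))
    expect_equal(cls$mvpa_min, sum(worn > 2241))
  }
})

test_that("standardization scales to the 735-min day", {
  expect_equal(standardize_day(60, 735), 60)
  expect_equal(standardize_day(60, 612.5), 72)  # 60 * 735 / 612.5
  expect_error(standardize_day(10, 0), class = "accel_argument_error")

  set.seed(31)
  for (i in 1:100) {
    reg <- runif(1, 600, 900)
    parts <- as.vector(stats::rmultinom(1, round(reg), c(0.5, 0.4, 0.1)))
    std <- standardize_day(parts, sum(parts))
    expect_equal(sum(std), 735)
  }
  # scale-correctness: doubling wear with identical composition
  expect_equal(standardize_day(c(300, 200, 100), 600),
               standardize_day(c(600, 400, 200), 1200))
})

test_that("largest-remainder rounding preserves the 735 total", {
  set.seed(5)
  for (i in 1:50) {
    x <- as.vector(stats::rmultinom(1, 7350, runif(3))) / 10
    r <- round_to_standard_day(x)
    expect_equal(sum(r), 735L)
    expect_true(all(abs(r - x) <= 1))
  }
})

test_that("child summaries pool cpm, average standardized days, apply the inclusive 60-min boundary", {
  mk_day <- function(date, reg, sed, light, mvpa, counts, steps) {
    tibble::tibble(child_id = "c", date = as.Date(date),
                   registered_minutes = reg,
                   waking_registered_minutes = reg, counts_sum = counts,
                   steps_sum = steps, n_spurious = 0, is_wear_day = TRUE,
                   is_valid_day = reg >= 600, exclusion_reason = "",
                   sedentary_min = sed, light_min = light, mvpa_min = mvpa)
  }
  days <- dplyr::bind_rows(
    mk_day("2008-06-02", 735, 400, 285, 50, 450000, 9000),
    mk_day("2008-06-03", 735, 380, 285, 70, 430000, 11000)
  )
  sm <- summarize_child(days)
  expect_equal(sm$mvpa_min_day, 60)
  expect_true(sm$meets_guideline)  # exactly 60 meets the guideline
  expect_equal(sm$mean_cpm, (450000 + 430000) / (735 + 735))
  expect_equal(sm$steps_day, 10000)

  # identical days reproduce the single-day values
  same <- dplyr::bind_rows(mk_day("2008-06-02", 700, 350, 300, 50, 420000, 9500),
                           mk_day("2008-06-03", 700, 350, 300, 50, 420000, 9500))
  sm2 <- summarize_child(same)
  expect_equal(sm2$mvpa_min_day, 50 * 735 / 700)
  expect_equal(sm2$sedentary_hours_day, 350 * (735 / 700) / 60)

  # pooled cpm is not the mean of daily cpm
  uneq <- dplyr::bind_rows(mk_day("2008-06-02", 600, 400, 150, 50, 100000, 5000),
                           mk_day("2008-06-03", 900, 500, 330, 70, 600000, 12000))
  sm3 <- summarize_child(uneq)
  expect_equal(sm3$mean_cpm, 700000 / 1500)
  expect_false(isTRUE(all.equal(sm3$mean_cpm,
                                mean(c(100000 / 600, 600000 / 900)))))

  expect_error(summarize_child(days[1, ]), class = "accel_argument_error")
})

test_that("mean_cpm matches a ratio oracle on random children", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    reg <- runif(k, 620, 850)
    counts <- runif(k, 2e5, 6e5)
    days <- tibble::tibble(
      child_id = "c", date = as.Date("2008-06-02") + seq_len(k) - 1,
      registered_minutes = reg, waking_registered_minutes = reg,
      counts_sum = counts, steps_sum = runif(k, 5e3, 1.5e4),
      n_spurious = 0, is_wear_day = TRUE, is_valid_day = TRUE,
      exclusion_reason = "",
      sedentary_min = reg * 0.5, light_min = reg * 0.4, mvpa_min = reg * 0.1
    )
    sm <- summarize_child(days)
    expect_equal(sm$mean_cpm, sum(counts) / sum(reg))
  }
})

test_that("cut-point sensitivity is monotone and consistent with the main run", {
  coh <- simulate_cohort(simulation_config(n_children = 25, seed = 13))
  red <- reduce_cohort(coh$epochs)
  tab <- cohort_table(red$summaries, coh$meta)
  sens <- cutpoint_sensitivity(red, coh$meta, c(2000, 2241, 3000))
  expect_setequal(unique(sens$threshold), c(2000, 2241, 3000))

  wide <- tidyr::pivot_wider(sens, id_cols = "gender",
                             names_from = "threshold",
                             values_from = "prevalence")
  expect_true(all(wide$`2000` >= wide$`2241`))
  expect_true(all(wide$`2241` >= wide$`3000`))

  # default threshold reproduces the main-run prevalences bit for bit
  main <- dplyr::summarise(
    dplyr::group_by(tab, gender),
    prevalence = weighted.mean(meets_guideline, sampling_weight),
    .groups = "drop"
  )
  at_default <- dplyr::arrange(sens[sens$threshold == 2241,
                                    c("gender", "prevalence")], gender)
  expect_identical(dplyr::arrange(main, gender)$prevalence,
                   at_default$prevalence)

  expect_error(cutpoint_sensitivity(red, coh$meta, c(50, 2241)),
               class = "accel_argument_error")
})

test_that("per-child MVPA minutes never increase as the cut-point rises", {
  coh <- simulate_cohort(simulation_config(n_children = 6, seed = 17))
  red <- reduce_cohort(coh$epochs)
  per_thr <- lapply(c(2000, 2241, 3000), function(thr) {
    cuts <- cut_points(100, thr)
    purrr::map_dfr(red$epochs, function(ep) {
      cls <- classify_intensity(ep, cuts)
      tibble::tibble(child_id = ep$child_id[1], mvpa = sum(cls$mvpa_min))
    })
  })
  expect_true(all(per_thr[[1]]$mvpa >= per_thr[[2]]$mvpa))
  expect_true(all(per_thr[[2]]$mvpa >= per_thr[[3]]$mvpa))
})
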