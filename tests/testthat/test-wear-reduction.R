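cfg <- reduction_config()

test_that("spurious flagging includes the threshold boundary", {
  s <- flag_spurious(minute_series(c(500, 11715, 500)))
  expect_equal(as.character(s$wear), c("WORN", "SPURIOUS", "WORN"))
  s0 <- flag_spurious(minute_series(rep(0, 10)))
  expect_true(all(s0$wear == "WORN"))
  s1 <- flag_spurious(minute_series(c(11714, 11716)))
  expect_equal(as.character(s1$wear), c("WORN", "SPURIOUS"))
})

test_that("non-wear uses the 20-min inclusive boundary", {
  z20 <- minute_series(c(5, rep(0, 20), 5))
  m <- detect_nonwear(flag_spurious(z20))
  expect_equal(sum(m$wear == "NONWEAR"), 20L)
  z19 <- minute_series(c(5, rep(0, 19), 5))
  m19 <- detect_nonwear(flag_spurious(z19))
  expect_true(all(m19$wear == "WORN"))
})

test_that("spurious epochs break zero runs", {
  # 12 zeros + spurious + 12 zeros: no run reaches 20 min
  s <- minute_series(c(rep(0, 12), 20000, rep(0, 12)))
  m <- detect_nonwear(flag_spurious(s))
  expect_equal(sum(m$wear == "NONWEAR"), 0L)
  expect_equal(sum(m$wear == "SPURIOUS"), 1L)
  # without the spurious break the 25 zeros would be one non-wear run
  s2 <- minute_series(rep(0, 25))
  m2 <- detect_nonwear(flag_spurious(s2))
  expect_equal(sum(m2$wear == "NONWEAR"), 25L)
})

test_that("non-wear detection is idempotent", {
  set.seed(11)
  counts <- ifelse(runif(2000) < 0.55, 0, rpois(2000, 300))
  m1 <- detect_nonwear(flag_spurious(minute_series(counts)))
  m2 <- detect_nonwear(m1)
  expect_identical(m1$wear, m2$wear)
})

test_that("a zero run spanning midnight is one run for detection but split for day accounting", {
  # 23:50-00:10: 20 zero minutes across midnight
  counts <- c(rep(100, 10), rep(0, 20), rep(100, 10))
  s <- minute_series(counts, start = "2008-06-02 23:40:00")
  m <- detect_nonwear(flag_spurious(s))
  expect_equal(sum(m$wear == "NONWEAR"), 20L)
  days <- registered_time(m, cfg)
  expect_equal(nrow(days), 2L)
  expect_equal(days$registered_minutes, c(10, 10))
})

test_that("mask agrees with the run-length scan oracle on random sequences", {
  set.seed(101)
  for (rep_i in 1:300) {
    n <- sample(40:200, 1)
    p_zero <- runif(1, 0.2, 0.9)
    counts <- ifelse(runif(n) < p_zero, 0,
                     sample(c(1, 50, 500, 3000, 12000), n, replace = TRUE))
    s <- detect_nonwear(flag_spurious(minute_series(counts)))
    eligible <- counts < 11715
    expect_identical(s$wear == "NONWEAR", oracle_nonwear(counts, eligible),
                     info = paste("rep", rep_i))
    expect_identical(s$wear == "SPURIOUS", oracle_spurious(counts),
                     info = paste("rep", rep_i))
  }
})

test_that("registered time counts worn minutes only and conserves totals", {
  counts <- rep(200, 720)  # 08:00-20:00 fully worn
  s <- detect_nonwear(flag_spurious(minute_series(counts, "2008-06-02 08:00:00")))
  d <- registered_time(s, cfg)
  expect_equal(d$registered_minutes, 720)
  expect_equal(d$counts_sum, 200 * 720)

  z <- detect_nonwear(flag_spurious(minute_series(rep(0, 1440))))
  dz <- registered_time(z, cfg)
  expect_equal(dz$registered_minutes, 0)
  expect_equal(dz$exclusion_reason, "no_wear")

  set.seed(12)
  counts <- ifelse(runif(3000) < 0.5, 0, rpois(3000, 400))
  m <- detect_nonwear(flag_spurious(minute_series(counts)))
  dd <- registered_time(m, cfg)
  expect_equal(sum(dd$registered_minutes), sum(m$wear == "WORN"))
  expect_equal(sum(dd$counts_sum), sum(m$counts[m$wear == "WORN"]))
})

test_that("start/end detection follows the 150-min waking rule", {
  days <- tibble::tibble(
    child_id = "c", date = as.Date("2008-06-01") + 0:5,
    registered_minutes = c(30, 200, 400, 40, 300, 10),
    waking_registered_minutes = c(30, 200, 400, 40, 300, 10),
    counts_sum = 0, steps_sum = 0, n_spurious = 0,
    is_wear_day = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    is_valid_day = FALSE, exclusion_reason = ""
  )
  iv <- detect_start_end(days, cfg)
  expect_equal(iv$start_date, as.Date("2008-06-02"))
  expect_equal(iv$end_date, as.Date("2008-06-05"))

  all_ok <- dplyr::mutate(days, waking_registered_minutes = 200)
  iv2 <- detect_start_end(all_ok, cfg)
  expect_equal(iv2$start_date, min(days$date))
  expect_equal(iv2$end_date, max(days$date))

  none <- dplyr::mutate(days, waking_registered_minutes = 100)
  expect_true(is.na(detect_start_end(none, cfg)$start_date))
})

test_that("valid-day selection and inclusion match the enumeration oracle", {
  mk_days <- function(reg, wak) {
    tibble::tibble(
      child_id = "c", date = as.Date("2008-06-01") + seq_along(reg) - 1,
      registered_minutes = reg, waking_registered_minutes = wak,
      counts_sum = 0, steps_sum = 0, n_spurious = 0,
      is_wear_day = wak >= 150,
      is_valid_day = wak >= 150 & reg >= 600, exclusion_reason = ""
    )
  }
  d1 <- select_valid(mk_days(c(660, 540, 720), c(660, 540, 720)), cfg)
  expect_equal(sum(d1$is_valid_day), 2L)
  expect_true(attr(d1, "child_included"))

  d2 <- select_valid(mk_days(660, 660), cfg)
  expect_false(attr(d2, "child_included"))
  expect_equal(attr(d2, "child_exclusion_reason"), "insufficient_valid_days")

  set.seed(202)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    reg <- sample(c(0, 100, 400, 599, 600, 650, 900), k, replace = TRUE)
    wak <- pmin(reg, sample(c(0, 100, 149, 150, 400, 900), k, replace = TRUE))
    days <- mk_days(reg, wak)
    got <- select_valid(days, cfg)
    want <- oracle_inclusion(reg, wak)
    expect_equal(got$is_valid_day, want$valid, info = paste("case", i))
    expect_equal(attr(got, "child_included"), want$included,
                 info = paste("case", i))
  }
})

test_that("excluded days outside start/end carry a machine-readable reason", {
  days <- tibble::tibble(
    child_id = "c", date = as.Date("2008-06-01") + 0:3,
    registered_minutes = c(30, 700, 700, 20),
    waking_registered_minutes = c(30, 650, 650, 20),
    counts_sum = 0, steps_sum = 0, n_spurious = 0,
    is_wear_day = c(FALSE, TRUE, TRUE, FALSE),
    is_valid_day = c(FALSE, TRUE, TRUE, FALSE), exclusion_reason = ""
  )
  out <- select_valid(days, cfg)
  expect_equal(out$exclusion_reason[c(1, 4)],
               rep("outside_start_end", 2))
  expect_equal(out$exclusion_reason[2:3], c("", ""))
})

test_that("tightening thresholds never increases included children", {
  coh <- simulate_cohort(simulation_config(n_children = 15, seed = 31))
  base <- reduce_cohort(coh$epochs)
  n_base <- sum(base$inclusion$included)
  for (strict in list(reduction_config(validday_min_hours = 11),
                      reduction_config(min_valid_days = 4),
                      reduction_config(wearday_min_minutes = 300))) {
    n_strict <- sum(reduce_cohort(coh$epochs, strict)$inclusion$included)
    expect_lte(n_strict, n_base)
  }
})

test_that("reduction operations refuse sub-minute epochs", {
  es <- epoch_series("c", "2008-06-02 07:00:00", 15, counts = rep(1, 8),
                     steps = rep(0, 8))
  expect_error(flag_spurious(es), class = "accel_argument_error")
  expect_error(detect_nonwear(es), class = "accel_argument_error")
})
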