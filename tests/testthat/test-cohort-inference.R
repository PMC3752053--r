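test_that("season boundaries follow the astronomical convention", {
  expect_equal(as.character(season_of(as.Date("2008-03-21"))), "spring")
  expect_equal(as.character(season_of(as.Date("2008-06-20"))), "spring")
  expect_equal(as.character(season_of(as.Date("2008-06-21"))), "summer")
  expect_equal(as.character(season_of(as.Date("2008-09-20"))), "summer")
  expect_equal(as.character(season_of(as.Date("2008-09-21"))), "autumn")
  expect_equal(as.character(season_of(as.Date("2008-12-20"))), "autumn")
  expect_equal(as.character(season_of(as.Date("2008-12-21"))), "winter")
  expect_equal(as.character(season_of(as.Date("2009-03-20"))), "winter")
})

test_that("a non-leap year partitions into four seasons of the right sizes", {
  days <- seq(as.Date("2009-01-01"), as.Date("2009-12-31"), by = "day")
  tab <- table(season_of(days))
  # brute-force date arithmetic: interval lengths of the printed windows
  expect_equal(unname(tab["spring"]),
               as.integer(as.Date("2009-06-20") - as.Date("2009-03-21")) + 1L)
  expect_equal(unname(tab["summer"]),
               as.integer(as.Date("2009-09-20") - as.Date("2009-06-21")) + 1L)
  expect_equal(unname(tab["autumn"]),
               as.integer(as.Date("2009-12-20") - as.Date("2009-09-21")) + 1L)
  expect_equal(sum(tab), 365L)
})

test_that("weighted quantiles use the inverse-CDF rule", {
  expect_equal(unname(weighted_quantile(c(1, 2, 3), probs = 0.5)), 2)
  expect_equal(unname(weighted_quantile(c(1, 2), w = c(3, 1), probs = 0.5)), 1)
  expect_error(weighted_quantile(numeric(0)), class = "accel_argument_error")
  expect_error(weighted_quantile(1:3, w = c(1, -1, 1)),
               class = "accel_argument_error")

  set.seed(41)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    x <- round(rnorm(n, 100, 30), 1)
    w <- runif(n, 0.1, 5)
    p <- runif(1, 0.05, 0.95)
    expect_equal(unname(weighted_quantile(x, w, p)), oracle_wq(x, w, p),
                 info = paste("rep", i))
  }
  # equal weights reduce to type-1 sample quantiles
  x <- c(4, 8, 15, 16, 23, 42)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(weighted_quantile(x, probs = p)),
                 unname(quantile(x, p, type = 1)))
  }
})

test_that("estimators are invariant to rescaling all weights", {
  set.seed(51)
  x <- rlnorm(200, 4, 0.5)
  w <- runif(200, 0.5, 2)
  expect_equal(weighted_quantile(x, w), weighted_quantile(x, 13.7 * w))
  df <- tibble::tibble(y = x, sampling_weight = w,
                       season = sample(season_levels(), 200, replace = TRUE),
                       g = sample(c("a", "b"), 200, replace = TRUE))
  q1 <- season_adjusted_quantiles(df, "y", by = "g")
  df2 <- dplyr::mutate(df, sampling_weight = sampling_weight * 0.2)
  q2 <- season_adjusted_quantiles(df2, "y", by = "g")
  expect_equal(q1$estimate, q2$estimate)
})

test_that("season adjustment is a no-op without confounding and reduces to weighted quantiles", {
  set.seed(61)
  # identical outcome distribution in all seasons: adjusted == unadjusted
  n <- 4000
  df <- tibble::tibble(
    y = rep(rlnorm(n / 4, 4, 0.4), 4),
    season = rep(season_levels(), each = n / 4),
    sampling_weight = 1,
    g = "all"
  )
  adj <- season_adjusted_quantiles(df, "y")
  unadj <- weighted_quantile(df$y, df$sampling_weight)
  expect_equal(adj$estimate, unname(unadj), tolerance = 1e-10)

  # single season present: exact reduction
  one <- dplyr::filter(df, season == "spring")
  adj1 <- season_adjusted_quantiles(one, "y")
  expect_equal(adj1$estimate,
               unname(weighted_quantile(one$y, one$sampling_weight)))
})

test_that("season adjustment recovers planted group medians under season confounding", {
  set.seed(71)
  # group A measured mostly in (high) summer, group B mostly in winter;
  # true season-free group medians are equal
  n <- 6000
  season_mult <- c(spring = 1, summer = 1.3, autumn = 1, winter = 0.75)
  g <- rep(c("A", "B"), each = n / 2)
  season <- ifelse(g == "A",
                   sample(season_levels(), n, TRUE, prob = c(.1, .7, .1, .1)),
                   sample(season_levels(), n, TRUE, prob = c(.1, .1, .1, .7)))
  df <- tibble::tibble(
    y = 60 * season_mult[season] * rlnorm(n, 0, 0.3),
    season = season, g = g, sampling_weight = 1
  )
  crude <- season_adjusted_quantiles(df, "y", by = "g", probs = 0.5)
  # crude medians differ materially...
  raw_a <- weighted_quantile(df$y[df$g == "A"], probs = 0.5)
  raw_b <- weighted_quantile(df$y[df$g == "B"], probs = 0.5)
  expect_gt(raw_a / raw_b, 1.15)
  # ...but the standardized ones agree within a few percent
  est <- setNames(crude$estimate, crude$group)
  expect_lt(abs(est["A"] / est["B"] - 1), 0.06)
})

test_that("adjusted prevalence reduces to the weighted crude prevalence", {
  set.seed(81)
  n <- 600
  df <- tibble::tibble(
    meets_guideline = runif(n) < 0.5,
    gender = sample(c("male", "female"), n, TRUE),
    season = factor(sample(season_levels(), n, TRUE)),
    sampling_weight = runif(n, 0.5, 2)
  )
  ov <- adjusted_prevalence(df, "meets_guideline", n_boot = 0)
  expect_equal(tidy(ov)$prevalence,
               weighted.mean(df$meets_guideline, df$sampling_weight),
               tolerance = 1e-9)
  # exposure-only model: level estimates equal crude level prevalences
  byg <- adjusted_prevalence(df, "meets_guideline", exposure = "gender",
                             n_boot = 0)
  crude <- dplyr::summarise(
    dplyr::group_by(df, gender),
    p = weighted.mean(meets_guideline, sampling_weight), .groups = "drop")
  got <- tidy(byg)
  expect_equal(setNames(got$prevalence, got$level)[crude$gender],
               setNames(crude$p, crude$gender), tolerance = 1e-7)
})

test_that("separation is reported as an estimation failure", {
  df <- tibble::tibble(
    meets_guideline = c(rep(TRUE, 20), rep(FALSE, 20)),
    gender = c(rep("male", 20), rep("female", 20)),
    sampling_weight = 1
  )
  expect_error(
    adjusted_prevalence(df, "meets_guideline", exposure = "gender",
                        n_boot = 0),
    class = "accel_estimation_error"
  )
})

test_that("BH step-up matches the hand computation and the definitional oracle", {
  out <- pairwise_bh(c(0.01, 0.02, 0.20))
  expect_equal(out$significant, c(TRUE, TRUE, FALSE))
  expect_equal(out$marker, c("a", "b", ""))
  expect_true(all(!pairwise_bh(rep(1, 8))$significant))
  expect_error(pairwise_bh(c(0.5, 1.2)), class = "accel_argument_error")

  set.seed(91)
  for (i in 1:500) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    expect_identical(pairwise_bh(p)$significant, oracle_bh_reject(p),
                     info = paste("rep", i))
  }
})

test_that("second-order region graph drops first-order neighbours and row-standardizes", {
  a <- england_region_adjacency()
  g <- region_graph(a, order = 2)
  expect_true(all(g$neighbours * a == 0))       # pure second order
  expect_true(all(diag(g$neighbours) == 0))
  rs <- rowSums(g$w)
  expect_true(all(abs(rs[rowSums(g$neighbours) > 0] - 1) < 1e-12))
  expect_error(region_graph(matrix(c(0, 1, 0, 0), 2, 2)),
               class = "accel_argument_error")
})

test_that("Moran's I has the right sign structure and matches the double-sum oracle", {
  # checkerboard on a 2-colourable cycle of 8 regions: negative I
  cyc <- matrix(0, 8, 8)
  for (i in 1:8) { j <- i %% 8 + 1; cyc[i, j] <- 1; cyc[j, i] <- 1 }
  g1 <- region_graph(cyc, order = 1)
  mi_neg <- morans_i(rep(c(1, -1), 4), g1, n_perm = 199, seed = 1)
  expect_lt(mi_neg$I, 0)
  # two smooth clusters on the same cycle: positive I
  mi_pos <- morans_i(c(5, 6, 7, 6, -5, -6, -7, -6), g1, n_perm = 199, seed = 1)
  expect_gt(mi_pos$I, 0)
  expect_error(morans_i(rep(3, 8), g1, n_perm = 99),
               class = "accel_estimation_error")

  set.seed(123)
  for (i in 1:50) {
    a <- matrix(0, 9, 9)
    while (all(a == 0)) {
      a[upper.tri(a)] <- rbinom(36, 1, 0.4)
      a <- a + t(a)
    }
    g <- region_graph(a, order = 1)
    x <- rnorm(9)
    mi <- morans_i(x, g, n_perm = 99, seed = i)
    expect_equal(mi$I, oracle_moran(x, g$w), tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(9)
  a <- england_region_adjacency()
  g <- region_graph(a, order = 2)
  x <- rnorm(9, 50, 10)
  mi <- morans_i(x, g, n_perm = 999, seed = 2)
  ref <- ape::Moran.I(x, g$w, scaled = FALSE)
  expect_equal(mi$I, ref$observed, tolerance = 1e-10)
  expect_equal(mi$expected, ref$expected, tolerance = 1e-12)
})

test_that("pairwise group tests flag a large planted difference and not a null one", {
  set.seed(140)
  n <- 400
  df <- tibble::tibble(
    g = rep(c("lo", "mid", "hi"), length.out = n),
    season = sample(season_levels(), n, TRUE),
    sampling_weight = 1
  )
  df$y <- c(lo = 40, mid = 41, hi = 80)[df$g] * rlnorm(n, 0, 0.2)
  pw <- pairwise_group_tests(df, "y", "g", type = "median",
                             n_boot = 199, seed = 3)
  pair_sig <- function(a, b) {
    any(pw$significant[(pw$level_a == a & pw$level_b == b) |
                         (pw$level_a == b & pw$level_b == a)])
  }
  expect_true(pair_sig("hi", "lo"))
  expect_false(pair_sig("lo", "mid"))
})
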