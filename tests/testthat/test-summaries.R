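hourly_times <- function(n, t0 = "2013-09-01", step_s = 600) {
  as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * step_s
}

fake_labels <- function(tags, times = hourly_times(length(tags)),
                        confidence = rep(1, length(tags))) {
  out <- data.frame(window_start = times, cluster = as.integer(factor(tags)),
                    confidence = confidence, tag = tags,
                    stringsAsFactors = FALSE)
  attr(out, "tag_map") <- c("deep-bout", "shallow-bout", "intermediate",
                            "near-surface-shallow")
  out
}

test_that("diurnal percentile tables tile the day and stay ordered", {
  tt <- hourly_times(24 * 6 * 3)   # three days of 10-min windows
  const <- diurnal_percentiles(tt, rep(4.2, length(tt)), bin_h = 3)
  expect_equal(const$bin_start_h, seq(0, 21, by = 3))
  expect_true(all(const$P5 == 4.2 & const$P50 == 4.2 & const$P75 == 4.2))
  expect_true(all(const$P5 <= const$P50 & const$P50 <= const$P75))

  # feature = hour of the window midpoint lands inside its own bin
  hrs <- (as.numeric(tt) / 3600 + 1800 / 2 / 3600) %% 24
  tab <- diurnal_percentiles(tt, hrs, bin_h = 3)
  expect_true(all(abs(tab$P50 - (tab$bin_start_h + 1.5)) <= 1.5))
  expect_error(diurnal_percentiles(tt, hrs, bin_h = 5), "divide")
})

test_that("day/night eCDFs detect shifts and nothing else", {
  tt <- hourly_times(24 * 6 * 4)
  set.seed(51)
  v <- stats::rnorm(length(tt))
  same <- day_night_ecdf(tt, v)
  n_side <- min(same$n_day, same$n_night)
  expect_lt(same$max_gap, 2 / sqrt(n_side) + 2 / sqrt(n_side))

  hrs <- (as.numeric(tt) / 3600 + 0.25) %% 24
  shifted <- v + 2 * (hrs >= 6 & hrs < 18)
  dn <- day_night_ecdf(tt, shifted)
  grid <- sort(unique(shifted))
  expect_true(all(dn$day(grid) <= dn$night(grid) + 1e-12))
  expect_gt(dn$max_gap, 0.5)

  expect_error(day_night_ecdf(tt[1:3], v[1:3]), "empty")
})

test_that("time budgets normalize and respect confidence filters", {
  tags <- rep(c("deep-bout", "shallow-bout", "intermediate",
                "near-surface-shallow"), each = 25)
  lab <- fake_labels(tags)
  b <- time_budget(lab)
  expect_equal(b$fraction, rep(0.25, 4))
  expect_equal(sum(b$fraction), 1, tolerance = 1e-9)
  expect_equal(attr(b, "bouts_fraction"), 0.5)

  soft <- fake_labels(tags, confidence = rep(0.8, length(tags)))
  empty <- time_budget(soft, min_confidence = 1.0)
  expect_true(attr(empty, "zero_denominator"))
  expect_true(all(is.na(empty$fraction)))
})

test_that("daypart partitions are row-normalized", {
  tags <- rep("intermediate", 24 * 6)
  lab <- fake_labels(tags)
  part <- daypart_partition(lab, bin_h = 3)
  expect_true(all(part$intermediate[part$n > 0] == 1))
  tags2 <- sample(c("deep-bout", "shallow-bout", "intermediate",
                    "near-surface-shallow"), 24 * 18, replace = TRUE)
  lab2 <- fake_labels(tags2, times = hourly_times(length(tags2)))
  part2 <- daypart_partition(lab2, bin_h = 3)
  sums <- rowSums(part2[, attr(lab2, "tag_map")])
  expect_equal(sums[part2$n > 0], rep(1, sum(part2$n > 0)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("cumulative tag counts accumulate presence", {
  tags <- rep(c("deep-bout", "intermediate"), 10)
  lab <- fake_labels(tags)
  none <- cumulative_tag_count(lab, "near-surface-shallow")
  expect_true(all(none$cumulative == 0))
  all_deep <- fake_labels(rep("deep-bout", 15))
  expect_equal(cumulative_tag_count(all_deep, "deep-bout")$cumulative, 1:15)
  expect_true(all(diff(cumulative_tag_count(lab, "deep-bout")$cumulative)
                  %in% c(0L, 1L)))
  expect_error(cumulative_tag_count(lab, "pelagic"), "unknown tag")
})

test_that("before/after medians recover an injected step", {
  tt <- hourly_times(24 * 6 * 20, t0 = "2013-09-01")
  split <- as.POSIXct("2013-09-11", tz = "UTC")
  set.seed(52)
  v <- 10 + stats::rnorm(length(tt))
  same <- before_after_median(tt, v, split, span_days = 10)
  expect_lt(abs(same$difference), 0.2)

  stepped <- v + 4 * (tt >= split)
  ba <- before_after_median(tt, stepped, split, span_days = 10, seed = 3)
  expect_equal(ba$difference, 4, tolerance = 0.3)
  expect_true(ba$ci[1] <= 4 && 4 <= ba$ci[2])
  expect_error(before_after_median(tt, v, split, span_days = 0), "positive")
})

# The constructed noon-rest diurnal signatures (midday energy minimum,
# midday near-surface peak, day-side low-energy dominance) are exercised
# at full scale in test-acceptance.R.
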