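test_that("simulator is reproducible and respects state depth laws", {
  cfg <- sim_config()
  a <- simulate_dive_record(cfg, duration = 86400, seed = 42)
  b <- simulate_dive_record(cfg, duration = 86400, seed = 42)
  expect_identical(a$record$depth, b$record$depth)
  expect_identical(a$trace$state, b$trace$state)
  c <- simulate_dive_record(cfg, duration = 86400, seed = 43)
  expect_false(identical(a$record$depth, c$record$depth))

  expect_equal(nrow(a$trace), a$record$n)
  expect_true(all(a$record$depth >= 0 & a$record$depth <= cfg$depth_cap))

  # a rest-only record stays within the rest depth law plus noise
  r_only <- simulate_dive_record(cfg, duration = 4 * 3600, seed = 5,
                                 initial_state = "R")
  cfg_r <- cfg
  # force the whole record into one long rest episode
  long_r <- sim_config(mean_duration = c(R = 5e5, I = 4400, Bs = 3100, Bd = 4500),
                       duration_floor = c(R = 4e5, I = 600, Bs = 1020, Bd = 2040))
  rr <- simulate_dive_record(long_r, duration = 86400, seed = 5,
                             initial_state = "R")
  expect_true(all(rr$trace$state == "R"))
  expect_lte(max(rr$record$depth), 15 + 3 * long_r$noise_sd)
})

test_that("deep bouts are deeper than shallow bouts, bout for bout", {
  cfg <- sim_config()
  sim <- simulate_dive_record(cfg, duration = 7 * 86400, seed = 2)
  ep <- attr(sim$trace, "episodes")
  bout_max <- function(state) {
    rows <- ep[ep$state == state, ]
    vapply(seq_len(nrow(rows)), function(i) {
      i0 <- rows$start_index[i]
      max(sim$record$depth[i0:min(sim$record$n, i0 + rows$n_samples[i] - 1L)])
    }, numeric(1))
  }
  deep <- bout_max("Bd")
  shallow <- bout_max("Bs")
  expect_gte(length(deep), 20)
  expect_gte(length(shallow), 20)
  expect_gt(stats::median(deep), stats::median(shallow))
})

test_that("vertical speeds stay within the configured envelope", {
  cfg <- sim_config()
  sim <- simulate_dive_record(cfg, duration = 2 * 86400, seed = 3)
  v <- vertical_speed(sim$record)
  expect_gte(mean(abs(v) <= cfg$max_speed + 3 * cfg$noise_sd), 0.95)
})

test_that("strong noon-rest forcing shifts rest into the midday bin", {
  cfg <- sim_config(diurnal_modulation = 0.9)
  wins <- 0L
  for (s in 1:10) {
    sim <- simulate_dive_record(cfg, duration = 3 * 86400, seed = 100 + s)
    hrs <- (as.numeric(record_times(sim$record)) / 3600) %% 24
    noon <- mean(sim$trace$state[hrs >= 12 & hrs < 15] == "R")
    night <- mean(sim$trace$state[hrs >= 0 & hrs < 3] == "R")
    if (noon > night) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("simulator rejects impossible configurations", {
  expect_error(sim_config(transition = matrix(0, 4, 4)), "unreachable")
  expect_error(simulate_dive_record(sim_config(), duration = 600), "one hour")
  expect_error(sim_config(mean_duration = c(R = 100, I = 4400, Bs = 3100,
                                            Bd = 4500)),
               "duration_floor")
})

test_that("stationary fractions form a distribution consistent with long runs", {
  cfg <- sim_config()
  f <- stationary_fractions(cfg)
  expect_equal(sum(f), 1)
  expect_true(all(f > 0))
  # long-run realized occupancy approaches the quasi-static prediction
  fr <- rowMeans(vapply(1:4, function(s) {
    sim <- simulate_dive_record(cfg, duration = 7 * 86400, seed = 200 + s)
    as.numeric(table(factor(sim$trace$state, levels = names(f))) /
                 nrow(sim$trace))
  }, numeric(4)))
  expect_lt(max(abs(fr - f)), 0.08)
})

test_that("benchmark series have their defining properties", {
  s <- benchmark_series("sine", 2000, list(A = 2, T = 100))
  expect_true(all(abs(s) <= 2 + 1e-12))
  w <- benchmark_series("white_noise", 1e5, seed = 4)
  expect_lt(abs(mean(w)), 4 / sqrt(1e5))
  a <- benchmark_series("ar1", 5000, list(phi = 0.5), seed = 5)
  expect_lt(abs(stats::cor(a[-1], a[-length(a)]) - 0.5), 0.1)
  lx <- benchmark_series("lorenz_x", 1e5, seed = 6)
  expect_true(all(lx >= -25 & lx <= 25))
  expect_error(benchmark_series("pink_noise", 2000), "unknown")
  expect_error(benchmark_series("sine", 10), "1000")
})
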