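test_that("Euclidean distance from the origin matches its definition", {
  cl <- cloud_from_matrix(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(euclidean_distance(cl), c(5, 0, sqrt(3)))

  # naive per-point recomputation agrees exactly
  set.seed(21)
  X <- matrix(stats::rnorm(300), ncol = 3)
  cl2 <- cloud_from_matrix(X)
  naive <- apply(X, 1, function(p) sqrt(sum(p^2)))
  expect_identical(euclidean_distance(cl2), naive)
})

test_that("kinetic energy measures phase-space speed", {
  still <- cloud_from_matrix(matrix(1, 5, 3))
  expect_equal(kinetic_energy(still)$E_k, rep(0, 4))

  two <- cloud_from_matrix(rbind(c(0, 0, 0), c(2, 0, 0)))
  ke <- kinetic_energy(two, dt_step = 1)
  expect_equal(ke$v, 2)
  expect_equal(ke$E_k, 2)

  # E_k is translation invariant, L is not
  set.seed(22)
  X <- matrix(stats::rnorm(60), ncol = 3)
  shifted <- X + 10
  expect_equal(kinetic_energy(cloud_from_matrix(X))$E_k,
               kinetic_energy(cloud_from_matrix(shifted))$E_k)
  expect_false(isTRUE(all.equal(euclidean_distance(cloud_from_matrix(X)),
                                euclidean_distance(cloud_from_matrix(shifted)))))
})

test_that("the Lyapunov estimator recovers divergence signs", {
  # stable limit cycle: exponent indistinguishable from zero
  T_ <- 200.37
  x <- sin(2 * pi * seq_len(8000) / T_)
  cl <- delay_embed(x, round(T_ / 4), 2)
  ly <- max_lyapunov(cl, mean_period = T_)
  expect_lt(abs(ly$lambda), 0.05 / T_)

  # contracting spiral: negative slope; its time reversal: positive
  t <- seq_len(4000)
  xd <- exp(-t / 1500) * sin(2 * pi * t / 200)
  cld <- delay_embed(xd, 50, 2)
  expect_lt(max_lyapunov(cld, mean_period = 200)$lambda, 0)
  clr <- delay_embed(rev(xd), 50, 2)
  expect_gt(max_lyapunov(clr, mean_period = 200)$lambda, 0)
})

test_that("correlation dimension matches known geometries", {
  set.seed(23)
  tl <- sort(stats::runif(3000))
  line <- cloud_from_matrix(cbind(3 * tl, 2 - tl, 0.5 * tl))
  dl <- correlation_dimension(line)
  expect_gt(dl$d, 0.9)
  expect_lt(dl$d, 1.1)

  noise <- cloud_from_matrix(matrix(stats::rnorm(9000), ncol = 3))
  dn <- correlation_dimension(noise)
  expect_gt(dn$d, 2.5)
  expect_lte(dn$d, 3.0)

  # pair-counting oracle agreement on the correlation sum itself
  sub <- cloud_from_matrix(noise$points[1:400, ])
  r_grid <- exp(seq(log(0.3), log(2), length.out = 10))
  res <- correlation_dimension(sub, r_grid = r_grid)
  oracle <- corr_sum_oracle(sub$points, r_grid)
  expect_equal(res$curve$C, oracle[oracle > 0], tolerance = 1e-12)

  # degenerate cloud
  flat <- cloud_from_matrix(matrix(1, 100, 3))
  df <- correlation_dimension(flat)
  expect_equal(df$d, 0)
  expect_equal(df$flag, "degenerate")

  # global rescaling leaves the log-log slope unchanged
  scaled <- cloud_from_matrix(noise$points * 12.5)
  expect_equal(correlation_dimension(scaled)$d, dn$d)
})

test_that("window arithmetic matches the sliding design", {
  expect_equal(n_windows(7171200, 1800, 600), 11950)
  expect_equal(n_windows(1800, 1800, 600), 1)
  expect_equal(n_windows(2399, 1800, 600), 1)
  expect_equal(n_windows(2400, 1800, 600), 2)
})

test_that("sliding features are complete, flagged and reproducible", {
  cfg <- sim_config()
  sim <- simulate_dive_record(cfg, duration = 6 * 3600, seed = 31)
  rec <- regularize(sim$record)
  f1 <- sliding_features(rec, tau = 255, m = 3)
  expect_equal(nrow(f1), n_windows(rec$n, 1800, 600))
  expect_true(all(c("L_med", "Ek_med", "lyap", "dim", "period_s", "flags")
                  %in% names(f1)))
  expect_true(all(f1$L_med >= 0))
  expect_true(all(is.na(f1$dim) | (f1$dim >= 0 & f1$dim <= 3)))
  # bit-for-bit reproducible: no hidden randomness
  f2 <- sliding_features(rec, tau = 255, m = 3)
  expect_identical(f1, f2)
})

test_that("rest-only records yield low-distance, low-energy windows", {
  quiet <- sim_config(mean_duration = c(R = 5e5, I = 4400, Bs = 3100, Bd = 4500),
                      duration_floor = c(R = 4e5, I = 600, Bs = 1020, Bd = 2040),
                      noise_sd = 0)
  sim <- simulate_dive_record(quiet, duration = 86400, seed = 32,
                              initial_state = "R")
  f <- sliding_features(regularize(sim$record), tau = 255, m = 3,
                        compute = character(0))
  expect_gte(mean(f$L_med < 20), 0.95)
  expect_gte(mean(f$Ek_med < 0.01), 0.95)
})

test_that("deep bouts carry more distance and energy than rest windows", {
  cfg <- sim_config()
  wins <- 0L
  for (s in 1:5) {
    sim <- simulate_dive_record(cfg, duration = 2 * 86400, seed = 400 + s)
    f <- sliding_features(regularize(sim$record), tau = 255, m = 3,
                          compute = character(0))
    truth <- window_truth(sim$trace, sim$record$n)
    if (!any(truth == "Bd") || !any(truth == "R")) next
    ok_L <- stats::median(f$L_med[truth == "Bd"]) >
      stats::median(f$L_med[truth == "Bs"])
    ok_E <- stats::median(f$Ek_med[truth == "Bd"]) >
      stats::median(f$Ek_med[truth == "R"])
    if (ok_L && ok_E) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
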