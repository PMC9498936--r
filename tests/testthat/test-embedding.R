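test_that("delay embedding reproduces the exact coordinate construction", {
  cl <- delay_embed(1:5, tau = 1, m = 3)
  expect_equal(cl$points,
               rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(cl$time_index, 1:3)

  cc <- delay_embed(rep(2.5, 10), tau = 2, m = 4)
  expect_true(all(cc$points == 2.5))
  expect_equal(nrow(cc$points), 10 - 3 * 2)

  # exhaustive identity on a random series
  set.seed(3)
  x <- stats::rnorm(60)
  cl2 <- delay_embed(x, tau = 4, m = 3)
  for (i in seq_len(nrow(cl2$points)))
    for (j in 1:3)
      expect_identical(cl2$points[i, j], x[i + (j - 1) * 4])

  expect_error(delay_embed(1:5, tau = 3, m = 3), "too short")
})

test_that("a quarter-period delay maps a sine onto a circle", {
  T_ <- 200
  x <- 3 * sin(2 * pi * seq_len(8000) / T_)
  cl <- delay_embed(x, tau = T_ / 4, m = 2)
  r <- euclidean_distance(cl)
  expect_lt(max(abs(r - 3)) / 3, 0.01)
})

test_that("auto-mutual information behaves as an information measure", {
  expect_warning(a0 <- auto_mutual_information(rep(1, 500), 0:10), "constant")
  expect_true(all(a0$ami == 0))

  # independence: small bias bound (n_bins-1)^2 / (2n) at these settings
  w <- benchmark_series("white_noise", 1e5, seed = 8)
  aw <- auto_mutual_information(w, c(1, 5, 20), n_bins = 16)
  expect_true(all(aw$ami >= 0))
  expect_true(all(aw$ami < 0.01))

  # exact recurrence: a period-T sawtooth has I(T) = I(0) when the joint
  # histogram is left undithered
  T_ <- 50
  saw <- (seq_len(5000) %% T_) / T_
  as <- auto_mutual_information(saw, c(0, T_), dither = FALSE)
  expect_equal(as$ami[2], as$ami[1], tolerance = 0.01)

  # reversal symmetry is exact by construction of the dither
  set.seed(9)
  x <- cumsum(stats::rnorm(3000))
  f <- auto_mutual_information(x, 0:30)$ami
  b <- auto_mutual_information(rev(x), 0:30)$ami
  expect_equal(f, b, tolerance = 1e-12)

  # affine rescaling leaves the curve unchanged (bins are scale-aware)
  y <- 5 * x + 3
  fy <- auto_mutual_information(y, 0:30)$ami
  expect_equal(f, fy, tolerance = 1e-10)
})

test_that("autocorrelation is normalized and matches analytic forms", {
  set.seed(10)
  x <- stats::rnorm(500)
  ac <- autocorrelation_curve(x, 20)
  expect_equal(ac$acf[1], 1)
  expect_error(autocorrelation_curve(rep(3, 100), 10), "constant")

  T_ <- 100
  s <- sin(2 * pi * seq_len(20000) / T_)
  acs <- autocorrelation_curve(s, 60)
  first_zero <- acs$lag[which(acs$acf < 0)[1]]
  expect_lte(abs(first_zero - T_ / 4), 1)
})

test_that("segment medians summarize per-segment delay curves", {
  # identical segments: median equals any single segment's curve
  seg <- 2 + sin(2 * pi * seq_len(600) / 60) + 0.1 * seq_len(600) %% 7
  rec <- make_record(rep(seg, 4))
  med <- segment_median_curve(rec, segment_s = 600, curve = "ami",
                              lags = 0:50)
  one <- auto_mutual_information(seg, 0:50)
  expect_equal(med$median, one$ami, tolerance = 1e-10)
  expect_equal(attr(med, "n_segments"), 4L)

  short <- make_record(seg)
  expect_error(segment_median_curve(short, segment_s = 600), "two segments")
})

test_that("delay selection finds the first prominent AMI minimum", {
  sel <- select_delay(list(ami = data.frame(lag = c(0, 100, 200, 300, 400),
                                            ami = c(3, 2, 1, 2, 3))))
  expect_equal(sel$tau_s, 200)
  expect_equal(sel$method, "ami_minimum")

  # monotone decreasing AMI: fall back to the ACF zero crossing, flagged
  sel2 <- select_delay(list(
    ami = data.frame(lag = 0:10 * 100, ami = seq(3, 1, length.out = 11)),
    acf = data.frame(lag = 0:10 * 100,
                     acf = c(1, 0.8, 0.5, 0.3, 0.1, -0.05, -0.2, -0.3,
                             -0.2, -0.1, 0))
  ))
  expect_equal(sel2$method, "acf_zero_fallback")
  expect_equal(sel2$tau_s, 500)

  expect_error(select_delay(list(
    ami = data.frame(lag = 0:5, ami = 6:1))), "no AMI local minimum")
})

test_that("FNN profiles separate deterministic signals from noise", {
  T_ <- 200
  x <- sin(2 * pi * seq_len(5000) / T_)
  prof <- false_nearest_fraction(x, T_ / 4, 1:5, theiler = T_)
  expect_lt(prof$fnn[2], 0.02)
  expect_equal(select_dimension(prof), 2)
  # monotone non-increasing for a noise-free deterministic signal
  expect_true(all(diff(prof$fnn) <= 1e-9))

  lx <- benchmark_series("lorenz_x", 6000, seed = 7)
  pl <- false_nearest_fraction(lx, 16, 1:5, theiler = 100)
  expect_true(all(diff(pl$fnn) <= 0.02))

  nz <- benchmark_series("white_noise", 5000, seed = 3)
  pn <- false_nearest_fraction(nz, 1, 1:5, theiler = 5)
  expect_true(all(pn$fnn > 0.2))

  # affine rescaling changes nothing (ratios and thresholds are scale-aware;
  # checked on aperiodic data where neighbor ties cannot flip)
  pl2 <- false_nearest_fraction(5 * lx + 2, 16, 1:5, theiler = 100)
  expect_equal(pl$fnn, pl2$fnn)
  expect_equal(select_dimension(pl, 0.05), select_dimension(pl2, 0.05))
})

test_that("dimension selection applies the threshold rule", {
  prof <- data.frame(m = 1:4, fnn = c(0.8, 0.3, 0.005, 0.004))
  expect_equal(select_dimension(prof, 0.01), 3)
  expect_equal(select_dimension(data.frame(m = 1:3, fnn = c(0, 0, 0))), 1)
  expect_error(select_dimension(data.frame(m = 1:3, fnn = c(0.9, 0.8, 0.7))),
               "no dimension")
})
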