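#' Time-delay embedding of a scalar series
#'
#' Builds the delay-coordinate state-space cloud
#' `y(i) = [x(i), x(i+tau), ..., x(i+(m-1)tau)]` from a depth record or a
#' plain numeric series. Coordinates are copied exactly from the series, no
#' interpolation.
#'
#' @param x a [depth_record()] (then `tau` is in seconds) or a numeric
#'   vector (then `tau` is in samples and `dt` defaults to 1).
#' @param tau embedding delay (seconds for a record, samples for a vector).
#' @param m embedding dimension (integer >= 1).
#' @param dt sample interval; taken from the record when `x` is one.
#' @return a `state_space_cloud`: list with `points` (matrix, one row per
#'   `y(i)`), `time_index` (sample index of `x(i)` for each point), `tau_s`,
#'   `tau_samples`, `m`, `dt`.
#' @export
delay_embed <- function(x, tau, m, dt = NULL) {
  if (inherits(x, "depth_record")) {
    series <- x$depth
    dt <- x$dt
    tau_samples <- as.integer(round(tau / dt))
  } else {
    series <- as.numeric(x)
    if (is.null(dt)) dt <- 1
    tau_samples <- as.integer(round(tau))
  }
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1")
  if (tau_samples < 1L) stop("tau must be at least one sample")
  n <- length(series)
  span <- (m - 1L) * tau_samples
  if (n <= span)
    stop(sprintf("series too short for embedding: need more than %d samples, have %d",
                 span, n))
  n_pts <- n - span
  pts <- matrix(0, nrow = n_pts, ncol = m)
  for (j in seq_len(m)) {
    off <- (j - 1L) * tau_samples
    pts[, j] <- series[(1L + off):(n_pts + off)]
  }
  structure(list(points = pts, time_index = seq_len(n_pts),
                 tau_s = tau_samples * dt, tau_samples = tau_samples,
                 m = m, dt = dt),
            class = "state_space_cloud")
}

#' @export
print.state_space_cloud <- function(x, ...) {
  cat(sprintf("<state_space_cloud> %d points in %dD (tau = %g s, dt = %g s)\n",
              nrow(x$points), x$m, x$tau_s, x$dt))
  invisible(x)
}

#' Lag grid for delay-selection curves
#'
#' Dense where the first auto-mutual-information minimum is expected
#' (1-sample steps up to 600 s), then 5-s steps out to `max_lag_s`.
#'
#' @param dt sample interval (s).
#' @param max_lag_s largest lag (s, default 1800).
#' @return integer vector of lags in samples (lag 0 included).
#' @export
default_lag_grid <- function(dt = 1, max_lag_s = 1800) {
  fine_max <- floor(min(600, max_lag_s) / dt)
  lags <- 0:fine_max
  if (max_lag_s > 600) {
    coarse <- seq(600 + 5, max_lag_s, by = 5) / dt
    lags <- c(lags, as.integer(round(coarse)))
  }
  unique(lags)
}

#' Auto-mutual information curve
#'
#' Histogram-based mutual information (nats) between `x(t)` and
#' `x(t + lag)` on an equal-width grid of `n_bins` bins spanning the range
#' of the series. For long series the pairs entering each joint histogram
#' are strided so at most `max_pairs` are used per lag; the bin grid stays
#' global, so the argmin location is unaffected.
#'
#' Noise-free deterministic signals (a pure sine, say) concentrate their
#' joint distribution on a measure-zero curve, which makes the binned
#' estimate jump as cell boundaries move with the lag; a deterministic
#' sub-bin dither (amplitude half a bin width, derived by hashing each
#' sample's value together with its distance from the nearer series end,
#' so that reversing the series reproduces the dither exactly) suppresses
#' these artifacts without touching the RNG state. The dither is
#' negligible for data whose own noise exceeds a bin width.
#'
#' @param series numeric vector.
#' @param lags integer lags in samples (0 allowed).
#' @param n_bins number of histogram bins per margin (default 64).
#' @param max_pairs cap on pairs per lag (default 2e5).
#' @param dither apply the deterministic sub-bin dither (default `TRUE`).
#' @return data frame with columns `lag` (samples) and `ami` (nats). A
#'   constant series yields an all-zero curve with a warning.
#' @export
auto_mutual_information <- function(series, lags, n_bins = 64, max_pairs = 2e5,
                                    dither = TRUE) {
  x <- as.numeric(series)
  n <- length(x)
  if (max(lags) >= n) stop("max lag must be smaller than the series length")
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant series: mutual information is identically zero")
    return(data.frame(lag = lags, ami = 0))
  }
  if (dither) {
    w <- diff(rng) / n_bins
    pos <- pmin(seq_len(n), n + 1L - seq_len(n))
    h <- sin(pos * 12.9898 + (x - rng[1L]) / diff(rng) * 78.233) * 43758.5453
    x <- x + (h - floor(h) - 0.5) * w
    rng <- range(x)
  }
  width <- diff(rng) / n_bins
  bin <- pmin(n_bins, 1L + as.integer(floor((x - rng[1L]) / width)))
  ami <- vapply(lags, function(lag) {
    np <- n - lag
    idx <- if (np > max_pairs) {
      as.integer(seq(1L, np, by = ceiling(np / max_pairs)))
    } else seq_len(np)
    bi <- bin[idx]
    bj <- bin[idx + lag]
    joint <- tabulate(bi + n_bins * (bj - 1L), nbins = n_bins * n_bins)
    N <- length(idx)
    pj <- joint / N
    px <- tabulate(bi, nbins = n_bins) / N
    py <- tabulate(bj, nbins = n_bins) / N
    nz <- which(joint > 0L)
    ix <- ((nz - 1L) %% n_bins) + 1L
    iy <- ((nz - 1L) %/% n_bins) + 1L
    sum(pj[nz] * log(pj[nz] / (px[ix] * py[iy])))
  }, numeric(1))
  data.frame(lag = as.integer(lags), ami = ami)
}

#' Autocorrelation curve
#'
#' Biased sample autocorrelation normalized to `R(0) = 1`
#' (via [stats::acf()]).
#'
#' @param series numeric vector.
#' @param max_lag largest lag in samples.
#' @return data frame with columns `lag` and `acf`.
#' @export
autocorrelation_curve <- function(series, max_lag) {
  x <- as.numeric(series)
  if (stats::var(x) == 0) stop("constant series: autocorrelation undefined")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  data.frame(lag = as.integer(a$lag[, 1, 1]), acf = as.numeric(a$acf[, 1, 1]))
}

#' Pointwise median of a per-segment delay curve
#'
#' Splits a record into non-overlapping segments (6 h by default), computes
#' the requested curve (AMI or ACF) on each, and returns the pointwise
#' median with interquartile spread. Segments with degenerate (zero)
#' variance are skipped and counted.
#'
#' @param record a regularized [depth_record()] covering at least two
#'   segments.
#' @param segment_s segment length in seconds (default 21600 = 6 h).
#' @param curve `"ami"` or `"acf"`.
#' @param lags lags in samples; defaults to [default_lag_grid()].
#' @param ... passed to the curve function (`n_bins`, `max_pairs`).
#' @return data frame `lag`, `median`, `q25`, `q75` with attributes
#'   `n_segments` (valid) and `n_skipped`.
#' @export
segment_median_curve <- function(record, segment_s = 21600,
                                 curve = c("ami", "acf"), lags = NULL, ...) {
  curve <- match.arg(curve)
  stopifnot(inherits(record, "depth_record"))
  seg_len <- floor(segment_s / record$dt)
  n_seg <- floor(record$n / seg_len)
  if (n_seg < 2L) stop("record shorter than two segments")
  if (is.null(lags)) {
    max_lag_s <- min(1800, (seg_len - 1) * record$dt / 2)
    lags <- default_lag_grid(record$dt, max_lag_s)
  }
  vals <- list()
  n_skipped <- 0L
  for (s in seq_len(n_seg)) {
    seg <- record$depth[((s - 1L) * seg_len + 1L):(s * seg_len)]
    if (stats::var(seg) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    vals[[length(vals) + 1L]] <- if (curve == "ami") {
      auto_mutual_information(seg, lags, ...)$ami
    } else {
      autocorrelation_curve(seg, max(lags))$acf[match(lags, 0:max(lags))]
    }
  }
  if (length(vals) < 2L) stop("fewer than 2 valid segments")
  M <- do.call(cbind, vals)
  out <- data.frame(
    lag = as.integer(lags),
    median = apply(M, 1, stats::median),
    q25 = apply(M, 1, stats::quantile, probs = 0.25),
    q75 = apply(M, 1, stats::quantile, probs = 0.75)
  )
  attr(out, "n_segments") <- length(vals)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select the embedding delay from AMI (with ACF cross-check)
#'
#' The delay is the lag of the first local minimum of the (median) AMI
#' curve after a 3-point moving-average smooth. To be robust against
#' estimator jitter, a minimum must be prominent: the smoothed curve must
#' rise at least 1% of its range above the candidate before any lower
#' value appears. When the basin around the minimum is wide (at least 5
#' lags below candidate + prominence), the lag is refined by a parabolic
#' fit over the basin, which recovers the vertex of the underlying smooth
#' curve to sub-jitter precision. If no prominent local minimum exists
#' within the lag range, the first zero crossing of the ACF curve is used
#' instead and flagged. The first negative ACF lag is always reported as a
#' cross-check.
#'
#' @param selection a list with element `ami` (data frame `lag` and `ami`,
#'   or `lag` and `median`) and optionally `acf` (data frame `lag`, `acf`
#'   or `lag`, `median`); lags in samples.
#' @param dt sample interval in seconds (default 1) used to express the
#'   result in seconds.
#' @param smooth odd moving-average width (default 3).
#' @return list with `tau_s`, `tau_samples`, `method` (`"ami_minimum"` or
#'   `"acf_zero_fallback"`), `acf_first_negative_s` (NA when no ACF given).
#' @export
select_delay <- function(selection, dt = 1, smooth = 3) {
  ami <- selection$ami
  if (is.null(ami)) stop("selection must contain an AMI curve")
  val <- if (!is.null(ami$ami)) ami$ami else ami$median
  lag <- ami$lag
  o <- order(lag)
  lag <- lag[o]; val <- val[o]
  s <- moving_average(val, smooth)
  n <- length(s)
  tau_samp <- NA_real_
  if (n >= 3L) {
    prom <- max(0.01 * diff(range(s)), 1e-12)
    cand <- NA_integer_
    cval <- Inf
    found <- NA_integer_
    for (i in 2:(n - 1L)) {
      if (s[i] < cval && s[i] < s[i - 1L]) {
        cand <- i
        cval <- s[i]
      }
      if (!is.na(cand) && s[i] > cval + prom) {
        found <- cand
        break
      }
    }
    if (!is.na(found)) {
      tau_samp <- lag[found]
      thr <- cval + prom
      a <- found
      while (a > 1L && s[a - 1L] <= thr) a <- a - 1L
      b <- found
      while (b < n && s[b + 1L] <= thr) b <- b + 1L
      if (b - a + 1L >= 5L) {
        ll <- lag[a:b]
        co <- stats::lm.fit(cbind(1, ll, ll^2), s[a:b])$coefficients
        if (is.finite(co[3L]) && co[3L] > 0) {
          v <- -co[2L] / (2 * co[3L])
          if (v >= lag[a] && v <= lag[b]) tau_samp <- v
        }
      }
    }
  }
  acf_neg <- NA_real_
  if (!is.null(selection$acf)) {
    av <- if (!is.null(selection$acf$acf)) selection$acf$acf else selection$acf$median
    al <- selection$acf$lag
    neg <- which(av < 0 & al > 0)
    if (length(neg) > 0) acf_neg <- al[neg[1L]] * dt
  }
  if (!is.na(tau_samp)) {
    tau_samp <- round(tau_samp)
    return(list(tau_s = tau_samp * dt, tau_samples = as.integer(tau_samp),
                method = "ami_minimum", acf_first_negative_s = acf_neg))
  }
  if (!is.na(acf_neg)) {
    return(list(tau_s = acf_neg, tau_samples = as.integer(round(acf_neg / dt)),
                method = "acf_zero_fallback", acf_first_negative_s = acf_neg))
  }
  stop("no AMI local minimum and no ACF zero crossing within the lag range")
}

moving_average <- function(x, width) {
  if (width < 2L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - (width %/% 2L))
    hi <- min(n, i + (width %/% 2L))
    mean(x[lo:hi])
  }, numeric(1))
}

#' False-nearest-neighbor fraction across embedding dimensions
#'
#' Kennel's criterion: for each point, find its exact nearest neighbor in
#' dimension `m` (excluding temporally close samples via a Theiler window)
#' and mark the pair false when the extra `(m+1)`-th-coordinate separation
#' exceeds `R_T` times the m-dimensional distance (distance-ratio test) or
#' when the `(m+1)`-dimensional separation exceeds `A_max` times the
#' attractor size (loneliness test, which keeps the fraction high for
#' noise that no added dimension can unfold). Ratios between numerically
#' identical recurrences of noise-free data are suppressed by an absolute
#' tolerance on the extra-coordinate separation. Long series are strided
#' down to at most `max_points` points; the Theiler exclusion uses
#' original sample indices so striding does not admit temporally adjacent
#' pairs.
#'
#' @param series numeric vector (or [depth_record()]).
#' @param tau delay in samples (seconds for a record).
#' @param m_range integer dimensions to profile (default 1:5).
#' @param R_T distance-ratio threshold (default 3).
#' @param theiler temporal exclusion half-width in samples; default
#'   `2 * tau` (about one dominant period when tau is a quarter period).
#' @param max_points stride cap on the number of points (default 1e4).
#' @param A_max loneliness threshold in units of the series' standard
#'   deviation (default 2); `NA` disables the loneliness test.
#' @param atol absolute extra-coordinate tolerance; default
#'   `1e-8 * sd(series)`.
#' @return data frame `m`, `fnn`, `n_valid` with attributes `R_T`,
#'   `theiler`, `stride`.
#' @export
false_nearest_fraction <- function(series, tau, m_range = 1:5, R_T = 3,
                                   theiler = NULL, max_points = 1e4,
                                   A_max = 2, atol = NULL) {
  if (inherits(series, "depth_record")) {
    tau <- round(tau / series$dt)
    series <- series$depth
  }
  x <- as.numeric(series)
  tau <- as.integer(round(tau))
  if (is.null(theiler)) theiler <- 2L * tau
  n <- length(x)
  m_range <- sort(as.integer(m_range))
  need <- (max(m_range)) * tau + 1L
  if (n <= need)
    stop(sprintf("series too short for FNN up to m = %d (need > %d samples)",
                 max(m_range), need))
  sd_x <- stats::sd(x)
  if (is.null(atol)) atol <- 1e-8 * sd_x
  ra <- if (is.na(A_max)) -1 else sd_x
  amax <- if (is.na(A_max)) 0 else A_max
  out <- data.frame(m = m_range, fnn = NA_real_, n_valid = NA_real_)
  stride_used <- 1L
  for (r in seq_along(m_range)) {
    m <- m_range[r]
    n_pts <- n - m * tau  # points that also have the (m+1)-th coordinate
    stride <- max(1L, ceiling(n_pts / max_points))
    stride_used <- max(stride_used, stride)
    idx <- seq.int(1L, n_pts, by = stride)
    X <- matrix(0, nrow = length(idx), ncol = m)
    for (j in seq_len(m)) X[, j] <- x[idx + (j - 1L) * tau]
    xnext <- x[idx + m * tau]
    res <- fnn_count_cpp(X, xnext, as.integer(idx), theiler, R_T, atol,
                         ra, amax)
    if (res$n_valid == 0)
      stop("too few points after Theiler exclusion")
    out$fnn[r] <- res$n_false / res$n_valid
    out$n_valid[r] <- res$n_valid
  }
  attr(out, "R_T") <- R_T
  attr(out, "theiler") <- theiler
  attr(out, "stride") <- stride_used
  out
}

#' Select the embedding dimension from an FNN profile
#'
#' @param profile data frame `m`, `fnn` as returned by
#'   [false_nearest_fraction()].
#' @param threshold FNN fraction below which a dimension is accepted
#'   (default 0.01).
#' @return the smallest `m` whose FNN fraction is below `threshold`.
#' @export
select_dimension <- function(profile, threshold = 0.01) {
  ok <- which(profile$fnn < threshold)
  if (length(ok) == 0L)
    stop(sprintf(
      "no dimension reaches FNN < %g; profile: %s", threshold,
      paste(sprintf("m=%d:%.3f", profile$m, profile$fnn), collapse = ", ")))
  profile$m[ok[1L]]
}
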