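#' Continuous wavelet scalogram of a series
#'
#' Analytic Morlet continuous wavelet transform (center frequency
#' `omega0 = 6`), computed in the Fourier domain with the standard
#' normalization under which white noise has a flat expected power across
#' scales. Scales are laid out as a log grid of periods with
#' `voices_per_octave` voices; the cone of influence (e-folding time
#' `sqrt(2) * scale`) is returned alongside.
#'
#' @param series numeric vector (regularized) or a [depth_record()].
#' @param dt sample interval (s); taken from the record when given one.
#' @param period_range 2-vector of periods (s); must lie inside
#'   `(2 dt, n dt / 2)`.
#' @param voices_per_octave voices per octave (default 12).
#' @return a `scalogram`: list with `periods` (s, increasing), `times`
#'   (s from record start), `power` (periods x times matrix, |W|^2), and
#'   `coi` (per-time maximum trustworthy period, s).
#' @export
cwt_power <- function(series, dt = 1, period_range = c(60, 21600),
                      voices_per_octave = 12) {
  if (inherits(series, "depth_record")) {
    dt <- series$dt
    series <- series$depth
  }
  x <- as.numeric(series)
  n <- length(x)
  check_period_range(period_range, n, dt)
  periods <- period_grid(period_range, voices_per_octave)
  xh <- stats::fft(x - mean(x))
  omega <- angular_frequencies(n, dt)
  power <- matrix(0, nrow = length(periods), ncol = n)
  for (s in seq_along(periods)) {
    power[s, ] <- Mod(morlet_coeffs(xh, omega, periods[s], dt, n))^2
  }
  edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  coi <- edge * morlet_fourier_factor() / sqrt(2)
  structure(list(periods = periods, times = (seq_len(n) - 1) * dt,
                 power = power, coi = coi, dt = dt),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d periods (%.0f-%.0f s) x %d times\n",
              length(x$periods), min(x$periods), max(x$periods),
              length(x$times)))
  invisible(x)
}

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

period_grid <- function(period_range, voices_per_octave) {
  2^(seq(log2(period_range[1]), log2(period_range[2]),
         by = 1 / voices_per_octave))
}

check_period_range <- function(period_range, n, dt) {
  if (length(period_range) != 2 || period_range[1] >= period_range[2])
    stop("period_range must be an increasing 2-vector")
  if (period_range[1] <= 2 * dt || period_range[2] >= n * dt / 2)
    stop(sprintf("period_range must lie inside (%g, %g) s", 2 * dt, n * dt / 2))
}

angular_frequencies <- function(n, dt) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2), -((n / 2) - 1):-1)
  2 * pi * k / (n * dt)
}

morlet_coeffs <- function(xh, omega, period, dt, n, omega0 = 6) {
  scale <- period / morlet_fourier_factor(omega0)
  daughter <- sqrt(2 * pi * scale / dt) * pi^(-0.25) *
    exp(-(scale * omega - omega0)^2 / 2) * (omega > 0)
  stats::fft(xh * daughter, inverse = TRUE) / n
}

#' Dominant period of a scalogram or series
#'
#' The period at which the time-averaged scalogram power is maximal. Times
#' where a scale lies outside its cone of influence are excluded from that
#' scale's average (scales with no valid time fall back to all times).
#' Given a plain series, the scalogram is computed first.
#'
#' @param x a `scalogram` from [cwt_power()], or a numeric series.
#' @param time_range optional 2-vector (s) restricting the average to a
#'   window of times.
#' @param ... passed to [cwt_power()] when `x` is a series.
#' @return dominant period in seconds.
#' @export
dominant_period <- function(x, time_range = NULL, ...) {
  if (!inherits(x, "scalogram")) x <- cwt_power(x, ...)
  keep_t <- rep(TRUE, length(x$times))
  if (!is.null(time_range))
    keep_t <- x$times >= time_range[1] & x$times <= time_range[2]
  if (!any(keep_t)) return(NA_real_)
  avg <- vapply(seq_along(x$periods), function(s) {
    ok <- keep_t & (x$coi >= x$periods[s])
    if (!any(ok)) ok <- keep_t
    mean(x$power[s, ok])
  }, numeric(1))
  x$periods[which.max(avg)]
}

# Windowed dominant periods from a single full-record CWT, computed
# scale-by-scale so the full power matrix is never materialized. Periods
# longer than the window are excluded from the per-window argmax (a cycle
# longer than the window is not observable within it), but the full grid
# enters the global time-averaged spectrum.
window_dominant_periods <- function(series, dt, starts, window_len,
                                    period_range = NULL, voices_per_octave = 12) {
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(period_range))
    period_range <- c(60, min(21600, floor(n * dt / 2) - 1))
  check_period_range(period_range, n, dt)
  periods <- period_grid(period_range, voices_per_octave)
  xh <- stats::fft(x - mean(x))
  omega <- angular_frequencies(n, dt)
  nw <- length(starts)
  win_power <- matrix(0, nrow = nw, ncol = length(periods))
  global_power <- numeric(length(periods))
  idx <- lapply(starts, function(s) s:(s + window_len - 1L))
  for (s in seq_along(periods)) {
    p <- Mod(morlet_coeffs(xh, omega, periods[s], dt, n))^2
    global_power[s] <- mean(p)
    win_power[, s] <- vapply(idx, function(i) mean(p[i]), numeric(1))
  }
  in_window <- periods <= window_len * dt
  if (!any(in_window)) in_window <- rep(TRUE, length(periods))
  dom <- periods[in_window][max.col(win_power[, in_window, drop = FALSE],
                                    ties.method = "first")]
  list(periods = periods, window_power = win_power, global_power = global_power,
       window_dominant = dom,
       global_dominant = periods[which.max(global_power)])
}
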