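#' Euclidean distance of each state-space point from the origin
#'
#' `L(t_i) = sqrt(sum_j y_j(i)^2)` — near zero during near-surface rest,
#' large during deep dive bouts.
#'
#' @param cloud a `state_space_cloud` from [delay_embed()].
#' @return numeric vector, one distance (m) per point.
#' @export
euclidean_distance <- function(cloud) {
  stopifnot(inherits(cloud, "state_space_cloud"))
  if (nrow(cloud$points) == 0L) stop("empty cloud")
  sqrt(rowSums(cloud$points^2))
}

#' Phase-space speed and kinetic energy along the trajectory
#'
#' The speed between consecutive points is the increment of distance in the
#' reconstructed space per unit time, `v_i = ||y(i+1) - y(i)|| / dt`, and
#' the kinetic-energy equivalent is `E_k = v^2 / 2` (units (m/s)^2). Zero
#' throughout is expected only for a dead or trapped animal.
#'
#' @param cloud a `state_space_cloud` with at least two points at uniform
#'   spacing.
#' @param dt_step time between consecutive points (s); defaults to the
#'   cloud's sample interval.
#' @return list with `v` and `E_k`, each of length `n_points - 1`.
#' @export
kinetic_energy <- function(cloud, dt_step = NULL) {
  stopifnot(inherits(cloud, "state_space_cloud"))
  if (is.null(dt_step)) dt_step <- cloud$dt
  n <- nrow(cloud$points)
  if (n < 2L) stop("need at least two points")
  d <- cloud$points[-1L, , drop = FALSE] - cloud$points[-n, , drop = FALSE]
  v <- sqrt(rowSums(d^2)) / dt_step
  list(v = v, E_k = v^2 / 2)
}

#' Maximum Lyapunov exponent (Rosenstein method)
#'
#' For each trajectory point, the nearest neighbor farther away in time
#' than `mean_period` is found (Theiler constraint), the mean logarithmic
#' pair separation `<ln d(k)>` is tracked over `k` forward steps, and the
#' exponent is the least-squares slope of that curve over `fit_range`,
#' divided by `dt`. Positive indicates divergence toward chaos, zero a
#' stable limit cycle, negative convergence.
#'
#' @param cloud a `state_space_cloud` (consecutive points).
#' @param dt time between consecutive points (s); defaults to the cloud's.
#' @param mean_period dominant period of the series (s), used as the
#'   Theiler window and to set the default fit horizon.
#' @param fit_range integer steps of the divergence curve to fit; default
#'   `1:round(mean_period / 2 / dt)`.
#' @return list with `lambda` (1/s), `curve` (data frame `k`, `mean_log`,
#'   `count`) and `n_pairs`.
#' @export
max_lyapunov <- function(cloud, dt = NULL, mean_period, fit_range = NULL) {
  stopifnot(inherits(cloud, "state_space_cloud"))
  if (is.null(dt)) dt <- cloud$dt
  n <- nrow(cloud$points)
  theiler <- mean_period / dt
  if (is.null(fit_range)) fit_range <- seq_len(max(3L, round(mean_period / 2 / dt)))
  kmax <- max(fit_range)
  if (n - kmax < 2L + 2 * theiler)
    stop("too few points for the Theiler window and divergence horizon")
  res <- rosenstein_curve_cpp(cloud$points, theiler, as.integer(kmax))
  if (res$n_pairs == 0) stop("no valid neighbors outside the Theiler window")
  mean_log <- res$mean_log
  ks <- fit_range[!is.na(mean_log[fit_range + 1L])]
  if (length(ks) < 3L) stop("fit region shorter than 3 points")
  y <- mean_log[ks + 1L]
  fit <- stats::lm.fit(cbind(1, ks * dt), y)
  list(lambda = unname(fit$coefficients[2L]),
       curve = data.frame(k = 0:kmax, mean_log = mean_log, count = res$count),
       n_pairs = res$n_pairs)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' The correlation sum `C(r)` counts pairs of points closer than `r`
#' (excluding temporally close pairs via a Theiler window); the dimension
#' is the slope of `log C(r)` vs `log r` over an automatically selected
#' scaling region -- the longest run of radii whose local slopes agree
#' within `slope_tol`. `d` is bounded by the embedding dimension, which
#' noise attains by filling the space.
#'
#' @param cloud a `state_space_cloud`.
#' @param r_grid radii; default 24 log-spaced radii between the 1st and
#'   50th percentile of pairwise distances (estimated on a subsample).
#' @param theiler temporal exclusion (samples between points).
#' @param n_r number of radii for the default grid.
#' @param slope_tol maximum local-slope spread within the scaling region.
#' @param min_run minimum number of consecutive slope intervals required.
#' @param fallback if `TRUE`, when no run satisfies `slope_tol`, use the
#'   longest-available window with minimal slope spread and flag the result
#'   instead of erroring.
#' @return list with `d`, `curve` (data frame `r`, `C`), `region` (indices
#'   used), and `flag` (`"ok"`, `"degenerate"`, or `"weak_scaling"`).
#' @export
correlation_dimension <- function(cloud, r_grid = NULL, theiler = 0, n_r = 24,
                                  slope_tol = 0.4, min_run = 4,
                                  fallback = FALSE) {
  stopifnot(inherits(cloud, "state_space_cloud"))
  X <- cloud$points
  n <- nrow(X)
  if (n < 10L) stop("too few points")
  if (is.null(r_grid)) {
    # the 1st/50th distance percentiles anchoring the radius grid are
    # stable under subsampling; 400 points give ~8e4 pairs
    sub <- X[as.integer(seq(1L, n, length.out = min(n, 400L))), , drop = FALSE]
    dd <- as.numeric(stats::dist(sub))
    dd <- dd[dd > 0]
    if (length(dd) == 0L)
      return(list(d = 0, curve = NULL, region = integer(0), flag = "degenerate"))
    qs <- stats::quantile(dd, c(0.01, 0.5))
    if (qs[1] <= 0) qs[1] <- min(dd)
    r_grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_r))
  }
  r_grid <- sort(r_grid)
  res <- corr_count_cpp(X, theiler, r_grid)
  if (res$n_pairs == 0) stop("no pairs outside the Theiler window")
  C <- res$count / res$n_pairs
  keep <- C > 0
  if (sum(keep) < min_run + 1L) {
    if (fallback)
      return(list(d = NA_real_, curve = data.frame(r = r_grid, C = C),
                  region = integer(0), flag = "weak_scaling"))
    stop("correlation sum empty over the radius grid; no scaling region")
  }
  lr <- log(r_grid[keep])
  lC <- log(C[keep])
  slopes <- diff(lC) / diff(lr)
  best <- scaling_region(slopes, slope_tol, min_run)
  flag <- "ok"
  if (is.null(best)) {
    if (!fallback) {
      stop(paste0("no scaling region with locally constant slope; ",
                  "correlation curve: ",
                  paste(sprintf("(%.3g, %.3g)", r_grid[keep], C[keep]),
                        collapse = " ")))
    }
    best <- widest_min_spread(slopes, min_run)
    flag <- "weak_scaling"
  }
  idx <- best[1L]:(best[2L] + 1L)  # slope intervals -> point indices
  fit <- stats::lm.fit(cbind(1, lr[idx]), lC[idx])
  d <- unname(fit$coefficients[2L])
  # the correlation exponent of an m-dimensional cloud cannot exceed m;
  # fits outside [0, m] are artifacts of a noisy correlation sum
  if (d < 0 || d > cloud$m) {
    d <- min(max(d, 0), cloud$m)
    flag <- "weak_scaling"
  }
  list(d = d,
       curve = data.frame(r = r_grid[keep], C = C[keep]),
       region = which(keep)[idx], flag = flag)
}

# longest run of consecutive slope intervals with max-min spread <= tol
scaling_region <- function(slopes, tol, min_run) {
  ns <- length(slopes)
  best <- NULL
  best_len <- min_run - 1L
  for (a in seq_len(ns)) {
    lo <- slopes[a]; hi <- slopes[a]
    for (b in a:ns) {
      lo <- min(lo, slopes[b]); hi <- max(hi, slopes[b])
      if (hi - lo > tol) break
      if (b - a + 1L > best_len) {
        best_len <- b - a + 1L
        best <- c(a, b)
      }
    }
  }
  best
}

widest_min_spread <- function(slopes, min_run) {
  ns <- length(slopes)
  run <- min(min_run, ns)
  spreads <- vapply(seq_len(ns - run + 1L), function(a) {
    w <- slopes[a:(a + run - 1L)]
    max(w) - min(w)
  }, numeric(1))
  a <- which.min(spreads)
  c(a, a + run - 1L)
}

#' Number of sliding windows over a record
#'
#' @param n_samples record length in samples.
#' @param window_samples window length in samples.
#' @param step_samples step between window starts in samples.
#' @return `floor((n_samples - window_samples) / step_samples) + 1`.
#' @export
n_windows <- function(n_samples, window_samples, step_samples) {
  floor((n_samples - window_samples) / step_samples) + 1
}

#' Sliding-window attractor features
#'
#' Embeds each 30-min window of the raw depth series (reusing the globally
#' selected delay and dimension) and computes the per-window invariants:
#' median and mean Euclidean distance `L`, median and mean kinetic energy
#' `E_k`, maximum Lyapunov exponent, correlation dimension, and dominant
#' wavelet period (from a single full-record CWT averaged over the window).
#' Estimator failures are recorded as missing values with a flag, never
#' fabricated.
#'
#' @param record a regularized [depth_record()].
#' @param tau embedding delay (s).
#' @param m embedding dimension.
#' @param window_s window length (s, default 1800).
#' @param step_s window step (s, default 600).
#' @param fallback_period Theiler/fit period (s) for windows whose own
#'   dominant period is unavailable (default 1020 s, the deep-bout cycle).
#' @param gap_flag_frac windows with more than this fraction of gap-filled
#'   samples are flagged (default 0.1).
#' @param compute which of the neighbor-based estimators to run
#'   (`"lyap"`, `"dim"`); distance, energy and period are always computed.
#' @return data frame with one row per window: `window_start` (POSIXct),
#'   `L_med`, `L_mean`, `Ek_med`, `Ek_mean`, `lyap`, `dim`, `period_s`,
#'   `flags`.
#' @export
sliding_features <- function(record, tau, m, window_s = 1800, step_s = 600,
                             fallback_period = 1020, gap_flag_frac = 0.1,
                             compute = c("lyap", "dim")) {
  stopifnot(inherits(record, "depth_record"))
  if (anyNA(record$depth)) stop("regularize the record first")
  dt <- record$dt
  W <- as.integer(round(window_s / dt))
  S <- as.integer(round(step_s / dt))
  if (record$n < W) stop("record shorter than one window")
  starts <- seq.int(1L, record$n - W + 1L, by = S)
  tau_samp <- as.integer(round(tau / dt))
  if (W <= (m - 1L) * tau_samp)
    stop("window shorter than the embedding span (m-1)*tau")

  wdp <- window_dominant_periods(record$depth, dt, starts, W)

  gap_frac <- numeric(length(starts))
  if (nrow(record$gap_log) > 0) {
    filled <- rep(FALSE, record$n)
    for (g in seq_len(nrow(record$gap_log))) {
      i0 <- record$gap_log$start_index[g]
      filled[i0:min(record$n, i0 + record$gap_log$length[g] - 1L)] <- TRUE
    }
    gap_frac <- vapply(starts, function(s0) mean(filled[s0:(s0 + W - 1L)]),
                       numeric(1))
  }

  nw <- length(starts)
  out <- data.frame(
    window_start = record$t0 + (starts - 1L) * dt,
    L_med = NA_real_, L_mean = NA_real_,
    Ek_med = NA_real_, Ek_mean = NA_real_,
    lyap = NA_real_, dim = NA_real_,
    period_s = wdp$window_dominant,
    flags = ""
  )
  for (w in seq_len(nw)) {
    seg <- record$depth[starts[w]:(starts[w] + W - 1L)]
    flags <- character(0)
    if (gap_frac[w] > gap_flag_frac) flags <- c(flags, "gapfilled")
    cloud <- delay_embed(seg, tau_samp, m, dt = dt)
    L <- euclidean_distance(cloud)
    out$L_med[w] <- stats::median(L)
    out$L_mean[w] <- mean(L)
    ke <- kinetic_energy(cloud)
    out$Ek_med[w] <- stats::median(ke$E_k)
    out$Ek_mean[w] <- mean(ke$E_k)
    period <- out$period_s[w]
    if (!is.finite(period) || period <= 0) period <- fallback_period
    # a Theiler window of a full dominant period would exclude nearly every
    # pair inside a two-period window; cap it at a quarter of the cloud
    period <- min(period, nrow(cloud$points) * dt / 4)
    if ("lyap" %in% compute) {
      ly <- tryCatch(max_lyapunov(cloud, dt = dt, mean_period = period),
                     error = function(e) NULL)
      if (is.null(ly)) flags <- c(flags, "lyap_failed")
      else out$lyap[w] <- ly$lambda
    }
    if ("dim" %in% compute) {
      cd <- tryCatch(correlation_dimension(cloud, theiler = period / dt,
                                           fallback = TRUE),
                     error = function(e) NULL)
      if (is.null(cd) || !is.finite(cd$d)) {
        flags <- c(flags, "dim_failed")
      } else {
        out$dim[w] <- cd$d
        if (cd$flag != "ok") flags <- c(flags, cd$flag)
      }
    }
    out$flags[w] <- paste(flags, collapse = ";")
  }
  attr(out, "params") <- list(tau_s = tau_samp * dt, m = m,
                              window_s = W * dt, step_s = S * dt,
                              global_dominant_period_s = wdp$global_dominant)
  out
}
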