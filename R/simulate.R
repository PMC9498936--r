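#' Configuration for the synthetic dive-record simulator
#'
#' The simulator emits a semi-Markov sequence of four behavioral states --
#' near-surface rest (`R`), intermediate near-surface activity (`I`),
#' shallow dive bouts (`Bs`) and deep dive bouts (`Bd`) -- and renders each
#' episode as a depth profile at 1 Hz. Bouts are trains of quasi-periodic
#' dive cycles (cosine-smoothed trapezoids: descent, bottom, ascent, surface
#' pause) with per-bout target depths and optional per-cycle depth drift
#' (telescopic spiral bouts); `R` is a slow low-amplitude wander near the
#' surface; `I` is irregular shallow dipping. Transition weights are
#' modulated sinusoidally by local hour of day so that rest is favored
#' around solar culmination.
#'
#' Defaults emulate a deep-diving odontocete record: deep-bout cycle period
#' 1020 s (17 min) to 250-600 m, shallow-bout period 510 s (8.5 min) to
#' 30-100 m, rest within 15 m of the surface, intermediate activity within
#' 50 m, vertical speeds bounded by 2 m/s, depth capped at 900 m.
#'
#' @param mean_duration named mean episode durations in seconds for
#'   `R`, `I`, `Bs`, `Bd`.
#' @param duration_floor named minimum episode durations (s); episode
#'   durations are floor + exponential.
#' @param dive_period named dive-cycle periods (s) for `Bs` and `Bd`.
#' @param depth_range named list of 2-vectors: per-bout target-depth law
#'   (uniform on the range) for `Bs`/`Bd`, wander/dip ranges for `R`/`I`.
#' @param depth_drift per-cycle drift magnitude of the bout target depth
#'   (m per cycle); the drift of each bout is drawn uniformly on
#'   `[-depth_drift, depth_drift]`.
#' @param max_speed nominal maximum vertical speed (m/s); descents and
#'   ascents run at 0.8 of this.
#' @param diurnal_modulation amplitude in `[0, 1)` of the sinusoidal
#'   modulation of transition weights (rest boosted, deep bouts suppressed,
#'   peaking at `diurnal_peak_hour`).
#' @param diurnal_peak_hour local hour at which rest is most favored.
#' @param noise_sd Gaussian observation noise on depth (m).
#' @param depth_cap hard cap on generated depth (m).
#' @param transition 4x4 row-stochastic base transition weight matrix over
#'   `R, I, Bs, Bd` with zero diagonal.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(mean_duration = c(R = 2000, I = 4400, Bs = 3100, Bd = 4500),
                       duration_floor = c(R = 600, I = 600, Bs = 1020, Bd = 2040),
                       dive_period = c(Bs = 510, Bd = 1020),
                       depth_range = list(R = c(0, 15), I = c(15, 50),
                                          Bs = c(30, 100), Bd = c(250, 600)),
                       depth_drift = 5,
                       max_speed = 2,
                       diurnal_modulation = 0.6,
                       diurnal_peak_hour = 13.5,
                       noise_sd = 0.5,
                       depth_cap = 900,
                       transition = NULL) {
  states <- c("R", "I", "Bs", "Bd")
  if (is.null(transition)) {
    transition <- rbind(
      R  = c(R = 0.0, I = 0.2, Bs = 0.3, Bd = 0.5),
      I  = c(R = 0.3, I = 0.0, Bs = 0.3, Bd = 0.4),
      Bs = c(R = 0.3, I = 0.3, Bs = 0.0, Bd = 0.4),
      Bd = c(R = 0.3, I = 0.4, Bs = 0.3, Bd = 0.0)
    )
  }
  stopifnot(
    all(states %in% names(mean_duration)),
    all(states %in% names(duration_floor)),
    all(c("Bs", "Bd") %in% names(dive_period)),
    all(states %in% names(depth_range)),
    all(mean_duration > 0), all(dive_period > 0),
    all(unlist(depth_range) >= 0),
    noise_sd >= 0, max_speed > 0, depth_cap > 0,
    diurnal_modulation >= 0, diurnal_modulation < 1,
    is.matrix(transition), all(dim(transition) == c(4, 4)),
    all(transition >= 0), all(diag(transition) == 0)
  )
  if (any(rowSums(transition) == 0))
    stop("unreachable state configuration: a row of transition weights is all zero")
  if (any(mean_duration[states] < duration_floor[states]))
    stop("mean_duration must be at least duration_floor for every state")
  structure(list(
    states = states,
    mean_duration = mean_duration[states],
    duration_floor = duration_floor[states],
    dive_period = dive_period,
    depth_range = depth_range[states],
    depth_drift = depth_drift,
    max_speed = max_speed,
    diurnal_modulation = diurnal_modulation,
    diurnal_peak_hour = diurnal_peak_hour,
    noise_sd = noise_sd,
    depth_cap = depth_cap,
    transition = transition
  ), class = "sim_config")
}

#' Stationary state fractions implied by a simulator configuration
#'
#' Occupancy fractions of the embedded semi-Markov chain: stationary
#' distribution of the transition matrix weighted by mean episode
#' durations. Because episode durations (about an hour) are short relative
#' to the 24-h modulation cycle, the diurnally modulated chain is treated
#' quasi-statically: the stationary occupancy is computed on a half-hour
#' grid of local hours and averaged over the day.
#'
#' @param config a [sim_config()].
#' @return named numeric vector over `R, I, Bs, Bd` summing to 1.
#' @export
stationary_fractions <- function(config) {
  occ_at <- function(W) {
    P <- W / rowSums(W)
    e <- eigen(t(P))
    p <- Re(e$vectors[, which.min(abs(e$values - 1))])
    p <- p / sum(p)
    o <- p * config$mean_duration
    o / sum(o)
  }
  A <- config$diurnal_modulation
  if (A == 0) {
    occ <- occ_at(config$transition)
  } else {
    hours <- seq(0, 23.5, by = 0.5)
    occ <- rowMeans(vapply(hours, function(h) {
      W <- config$transition
      ph <- cos(2 * pi * (h - config$diurnal_peak_hour) / 24)
      W[, "R"] <- W[, "R"] * (1 + A * ph)
      W[, "Bd"] <- W[, "Bd"] * pmax(1 - A * ph, 0.05)
      occ_at(W)
    }, numeric(4)))
  }
  names(occ) <- config$states
  occ
}

# cosine-smoothed kernel smoothing, edge-padded with end values
smooth_profile <- function(x, width = 31L) {
  if (width < 3L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(width) / (width + 1))
  w <- w / sum(w)
  xp <- c(rep(x[1L], width), x, rep(x[length(x)], width))
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(width + 1L):(width + length(x))])
}

# one dive cycle: pause at surface, descent, bottom, ascent (piecewise linear)
dive_cycle_profile <- function(period, target, v_nominal, pause_frac = 0.12) {
  period <- max(4, round(period))
  pause <- max(20, round(pause_frac * period))
  td <- round(target / v_nominal)
  td <- min(td, floor((period - pause) / 2))
  td <- max(td, 1L)
  bottom <- period - pause - 2L * td
  c(rep(0, pause),
    seq(0, target, length.out = td + 1L)[-1L],
    rep(target, max(bottom, 0L)),
    seq(target, 0, length.out = td + 1L)[-1L])
}

# low-amplitude near-surface wander for the rest state: slow AR(1) (about a
# 10-min correlation time) so vertical speeds stay at resting, cm/s scale
rest_profile <- function(n, range) {
  rho <- exp(-1 / 600)
  u <- as.numeric(stats::filter(stats::rnorm(n, sd = 2.5 * sqrt(1 - rho^2)),
                                rho, method = "recursive"))
  pmin(pmax(mean(range) * 0.5 + u, range[1L]), range[2L])
}

#' Simulate a dive record with known behavioral ground truth
#'
#' Draws a semi-Markov state sequence (exponential-with-floor episode
#' durations, diurnally modulated transition weights), renders each episode
#' as a depth profile, smooths corners with a cosine kernel so vertical
#' speeds stay bounded and state-space orbits close, and adds Gaussian
#' observation noise. Fully reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param duration record length in seconds (at least one hour).
#' @param seed integer seed for all randomness.
#' @param t0 record start time (UTC).
#' @param dt sample interval (s, default 1).
#' @param initial_state optional starting state (`"R"`, `"I"`, `"Bs"`,
#'   `"Bd"`); by default drawn from the embedded chain's stationary
#'   distribution.
#' @return list with elements `record` (a [depth_record()]) and `trace`
#'   (a data frame `state` per sample plus attribute `episodes`, the
#'   per-episode metadata: state, start index, duration, target depth,
#'   cycle period, drift).
#' @export
simulate_dive_record <- function(config, duration = 7 * 86400, seed = 1,
                                 t0 = as.POSIXct("2013-08-20 00:00:00", tz = "UTC"),
                                 dt = 1, initial_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (duration < 3600) stop("duration must be at least one hour")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_total <- floor(duration / dt)
  t0 <- as.POSIXct(t0, tz = "UTC")
  v_nom <- 0.8 * config$max_speed
  states <- config$states

  hour_at <- function(i) {
    (as.numeric(t0) / 3600 + (i - 1) * dt / 3600) %% 24
  }
  mod_weights <- function(from, hour) {
    w <- config$transition[from, ]
    A <- config$diurnal_modulation
    if (A > 0) {
      phase <- cos(2 * pi * (hour - config$diurnal_peak_hour) / 24)
      w["R"] <- w["R"] * (1 + A * phase)
      w["Bd"] <- w["Bd"] * max(1 - A * phase, 0.05)
    }
    w
  }

  depth <- numeric(0)
  labels <- character(0)
  episodes <- list()
  # initial state from the unmodulated stationary episode frequencies
  P <- config$transition / rowSums(config$transition)
  e <- eigen(t(P))
  pi_embed <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_embed <- pmax(pi_embed / sum(pi_embed), 0)
  state <- if (!is.null(initial_state)) {
    match.arg(initial_state, states)
  } else {
    sample(states, 1, prob = pi_embed)
  }

  while (length(depth) < n_total) {
    start <- length(depth) + 1L
    floor_s <- config$duration_floor[[state]]
    dur <- floor_s + stats::rexp(1, 1 / (config$mean_duration[[state]] - floor_s + 1e-9))
    rng <- config$depth_range[[state]]
    if (state %in% c("Bs", "Bd")) {
      period <- config$dive_period[[state]]
      n_cycles <- max(2L, as.integer(round(dur / period)))
      target0 <- stats::runif(1, rng[1L], rng[2L])
      drift <- stats::runif(1, -config$depth_drift, config$depth_drift)
      prof <- unlist(lapply(seq_len(n_cycles), function(cy) {
        tgt <- min(max(target0 + (cy - 1) * drift, rng[1L]), rng[2L])
        dive_cycle_profile(period / dt, tgt, v_nom * dt)
      }))
      meta <- list(target = target0, period = period, drift = drift,
                   n_cycles = n_cycles)
    } else if (state == "I") {
      prof <- numeric(0)
      tgts <- numeric(0)
      while (length(prof) < dur / dt) {
        cyc_p <- stats::runif(1, 180, 420) / dt
        tgt <- stats::runif(1, rng[1L], rng[2L])
        tgts <- c(tgts, tgt)
        prof <- c(prof, dive_cycle_profile(cyc_p, tgt, v_nom * dt,
                                           pause_frac = 0.3))
      }
      meta <- list(target = stats::median(tgts), period = NA_real_,
                   drift = 0, n_cycles = length(tgts))
    } else { # R
      prof <- rest_profile(max(2L, as.integer(round(dur / dt))), rng)
      meta <- list(target = mean(rng) * 0.5, period = NA_real_, drift = 0,
                   n_cycles = 0L)
    }
    depth <- c(depth, prof)
    labels <- c(labels, rep(state, length(prof)))
    episodes[[length(episodes) + 1L]] <- data.frame(
      state = state, start_index = start, n_samples = length(prof),
      target_depth = meta$target, cycle_period = meta$period,
      drift = meta$drift, n_cycles = meta$n_cycles
    )
    w <- mod_weights(state, hour_at(length(depth) + 1L))
    if (sum(w) <= 0) stop("unreachable state configuration: all transition weights zero")
    state <- sample(states, 1, prob = w)
  }
  depth <- depth[seq_len(n_total)]
  labels <- labels[seq_len(n_total)]

  depth <- smooth_profile(depth, width = 31L)
  if (config$noise_sd > 0)
    depth <- depth + stats::rnorm(n_total, sd = config$noise_sd)
  depth <- pmin(pmax(depth, 0), config$depth_cap)

  rec <- depth_record(depth, t0 = t0, dt = dt)
  trace <- data.frame(state = labels, stringsAsFactors = FALSE)
  attr(trace, "episodes") <- do.call(rbind, episodes)
  list(record = rec, trace = trace)
}

#' Benchmark series for validating attractor-invariant estimators
#'
#' Standard test signals with known dynamics: a pure sine, i.i.d. Gaussian
#' noise, an AR(1) process, or the x-component of the Lorenz system
#' (sigma = 10, rho = 28, beta = 8/3) integrated with fixed-step 4th-order
#' Runge-Kutta at step 0.01.
#'
#' @param name one of `"sine"`, `"white_noise"`, `"ar1"`, `"lorenz_x"`.
#' @param n number of samples (at least 1000).
#' @param params named list: `A`, `T` (sine, in samples); `sd` (noise);
#'   `phi` (AR(1)); `sigma`, `rho`, `beta`, `step`, `init` (Lorenz).
#' @param seed integer seed (used by the stochastic generators).
#' @return numeric vector of length `n`.
#' @export
benchmark_series <- function(name, n, params = list(), seed = 1) {
  if (n < 1000) stop("n must be at least 1000")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  switch(name,
    sine = {
      A <- p("A", 1); T_ <- p("T", 100)
      A * sin(2 * pi * seq_len(n) / T_)
    },
    white_noise = stats::rnorm(n, sd = p("sd", 1)),
    ar1 = {
      phi <- p("phi", 0.9)
      as.numeric(stats::filter(stats::rnorm(n, sd = p("sd", 1)), phi,
                               method = "recursive"))
    },
    lorenz_x = {
      sigma <- p("sigma", 10); rho <- p("rho", 28); beta <- p("beta", 8 / 3)
      step <- p("step", 0.01); init <- p("init", c(1, 1, 1))
      f <- function(t, y, parms) {
        list(c(sigma * (y[2] - y[1]),
               y[1] * (rho - y[3]) - y[2],
               y[1] * y[2] - beta * y[3]))
      }
      out <- deSolve::ode(y = c(x = init[1], y = init[2], z = init[3]),
                          times = seq(0, by = step, length.out = n),
                          func = f, parms = NULL, method = "rk4")
      as.numeric(out[, "x"])
    },
    stop(sprintf("unknown benchmark series '%s'", name))
  )
}
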