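# Shared fixtures and independent brute-force oracles used across tests.

make_record <- function(depth, t0 = as.POSIXct("2013-09-01", tz = "UTC"),
                        dt = 1) {
  depth_record(depth, t0 = t0, dt = dt)
}

write_csv_record <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

cloud_from_matrix <- function(X, tau = 1L, dt = 1) {
  structure(list(points = X, time_index = seq_len(nrow(X)), tau_s = tau,
                 tau_samples = as.integer(tau), m = ncol(X), dt = dt),
            class = "state_space_cloud")
}

# plain-R exhaustive false-nearest-neighbor oracle, mirroring the Kennel
# criterion definition but implemented independently of the C++ kernel
fnn_oracle <- function(x, tau, m, R_T = 3, theiler = 0, A_max = 2,
                       atol = 1e-8 * stats::sd(x)) {
  n <- length(x)
  np <- n - m * tau
  X <- sapply(seq_len(m), function(j) x[seq_len(np) + (j - 1L) * tau])
  if (m == 1) X <- matrix(X, ncol = 1)
  xn <- x[seq_len(np) + m * tau]
  sdx <- stats::sd(x)
  nf <- 0L; nv <- 0L
  for (i in seq_len(np)) {
    d2 <- rowSums((X - matrix(X[i, ], np, m, byrow = TRUE))^2)
    d2[abs(seq_len(np) - i) <= theiler] <- Inf
    j <- which.min(d2)
    if (!is.finite(d2[j])) next
    nv <- nv + 1L
    dm <- sqrt(d2[j])
    extra <- abs(xn[i] - xn[j])
    false_nn <- FALSE
    if (extra > atol && (dm == 0 || extra / dm > R_T)) false_nn <- TRUE
    if (!false_nn && !is.na(A_max) &&
        sqrt(dm^2 + extra^2) / sdx > A_max) false_nn <- TRUE
    if (false_nn) nf <- nf + 1L
  }
  nf / nv
}

# plain-R pair-counting oracle for the correlation sum
corr_sum_oracle <- function(X, r_grid, theiler = 0) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  keep <- abs(row(D) - col(D)) > theiler & upper.tri(D)
  dd <- D[keep]
  vapply(r_grid, function(r) mean(dd <= r), numeric(1))
}

# majority ground-truth state of each sliding window
window_truth <- function(trace, n, window = 1800, step = 600) {
  starts <- seq.int(1L, n - window + 1L, by = step)
  vapply(starts, function(s0) {
    names(which.max(table(trace$state[s0:(s0 + window - 1L)])))
  }, character(1))
}

log_features <- function(features) {
  X <- as.matrix(features[, c("L_med", "Ek_med", "lyap", "dim")])
  X[, 1] <- log(X[, 1])
  X[, 2] <- log(X[, 2])
  X
}
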