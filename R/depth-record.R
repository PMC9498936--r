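#' Uniformly sampled depth record
#'
#' A `depth_record` holds a single-animal depth time series sampled on a
#' strictly uniform grid: start time `t0` (UTC), sample interval `dt`
#' (seconds), and a numeric vector of depths in meters, positive down.
#' This is the observable `x(t)` from which the behavioral state space is
#' reconstructed by time-delay embedding.
#'
#' Depths must be non-negative; small negative sensor readings (surface
#' noise down to -0.5 m) are clipped to 0, anything more negative is an
#' error. Missing samples (`NA`) are tolerated at construction and flagged,
#' but must be filled by [regularize()] before any downstream analysis.
#'
#' @param depth numeric vector of depths (m, positive down).
#' @param t0 start time, a `POSIXct` (converted to UTC) or anything
#'   `as.POSIXct()` accepts; defaults to 1970-01-01T00:00:00Z.
#' @param dt sample interval in seconds (default 1).
#' @param gap_log optional data frame describing filled/missing runs
#'   (columns `start_index`, `length`); maintained by the reader and
#'   [regularize()].
#' @return an object of class `depth_record` with fields `t0`, `dt`,
#'   `depth`, `n` and `gap_log`.
#' @export
depth_record <- function(depth, t0 = as.POSIXct("1970-01-01", tz = "UTC"),
                         dt = 1, gap_log = NULL) {
  if (length(depth) == 0L) stop("empty record")
  if (!is.numeric(depth)) stop("depth must be numeric")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number of seconds")
  t0 <- as.POSIXct(t0, tz = "UTC")
  attr(t0, "tzone") <- "UTC"
  depth <- as.numeric(depth)
  bad_neg <- which(depth < -0.5)
  if (length(bad_neg) > 0L)
    stop(sprintf("depth below -0.5 m at sample %d (%.2f m): not a surface artifact",
                 bad_neg[1L], depth[bad_neg[1L]]))
  depth[!is.na(depth) & depth < 0] <- 0
  if (any(is.nan(depth))) depth[is.nan(depth)] <- NA_real_
  if (any(is.infinite(depth))) stop("non-finite depth values")
  if (is.null(gap_log)) {
    gap_log <- na_run_log(depth)
  }
  structure(
    list(t0 = t0, dt = dt, depth = depth, n = length(depth), gap_log = gap_log),
    class = "depth_record"
  )
}

# runs of NA samples as a gap log
na_run_log <- function(depth) {
  idx <- is.na(depth)
  if (!any(idx)) {
    return(data.frame(start_index = integer(0), length = integer(0)))
  }
  r <- rle(idx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_index = starts[keep], length = r$lengths[keep])
}

#' @export
print.depth_record <- function(x, ...) {
  cat(sprintf("<depth_record> n = %d samples, dt = %g s (%.2f d)\n",
              x$n, x$dt, x$n * x$dt / 86400))
  cat(sprintf("  t0 = %s UTC\n", format(x$t0, "%Y-%m-%d %H:%M:%S")))
  dd <- x$depth[!is.na(x$depth)]
  if (length(dd) > 0)
    cat(sprintf("  depth range [%.1f, %.1f] m, %d missing\n",
                min(dd), max(dd), sum(is.na(x$depth))))
  if (nrow(x$gap_log) > 0)
    cat(sprintf("  %d gap run(s), longest %d samples\n",
                nrow(x$gap_log), max(x$gap_log$length)))
  invisible(x)
}

#' Sample timestamps of a depth record
#'
#' @param record a [depth_record()].
#' @return `POSIXct` vector of length `record$n`.
#' @export
record_times <- function(record) {
  record$t0 + (seq_len(record$n) - 1L) * record$dt
}

#' Read a depth record from CSV
#'
#' Accepts the two-column format `timestamp_utc,depth_m` (RFC-4180, header
#' required) where timestamps are either epoch seconds or ISO-8601 strings,
#' or a single `depth_m` column in which case `t0` and `dt` must be given.
#' Timestamps must be strictly increasing and lie on a uniform grid; runs of
#' missing samples can be expanded to `NA` (for [regularize()]) with
#' `expand_gaps = TRUE`, otherwise a gap is an error.
#'
#' @param path CSV file path.
#' @param t0,dt start time and sample interval, used (and required) for the
#'   single-column format; `dt` also overrides the grid check otherwise.
#' @param expand_gaps insert `NA` samples where timestamps skip grid points.
#' @return a [depth_record()]; gap locations are reported in `$gap_log`.
#' @export
read_depth_record <- function(path, t0 = NULL, dt = NULL, expand_gaps = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty record")
  if (ncol(df) == 1L) {
    if (is.null(t0) || is.null(dt))
      stop("single-column depth file requires t0 and dt")
    return(depth_record(df[[1L]], t0 = t0, dt = dt))
  }
  ts_raw <- df[[1L]]
  depth <- as.numeric(df[[2L]])
  if (is.numeric(ts_raw)) {
    tsec <- as.numeric(ts_raw)
    t0_abs <- as.POSIXct(tsec[1L], origin = "1970-01-01", tz = "UTC")
  } else {
    tt <- as.POSIXct(ts_raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
    if (any(is.na(tt))) stop("unparseable timestamps")
    tsec <- as.numeric(tt)
    t0_abs <- tt[1L]
  }
  d <- diff(tsec)
  if (any(d <= 0)) stop("non-monotone timestamps")
  step <- if (is.null(dt)) min(d) else dt
  rel <- (tsec - tsec[1L]) / step
  if (max(abs(rel - round(rel))) > 1e-6)
    stop("timestamps do not lie on a uniform grid; non-uniform sampling; regularize required")
  rel <- round(rel)
  if (any(diff(rel) != 1)) {
    if (!expand_gaps)
      stop("non-uniform sampling; regularize required (gaps in timestamp grid; use expand_gaps = TRUE)")
    full <- rep(NA_real_, rel[length(rel)] + 1L)
    full[rel + 1L] <- depth
    depth <- full
  }
  depth_record(depth, t0 = t0_abs, dt = step)
}

#' Write a depth record to CSV
#'
#' Mirrors [read_depth_record()]: header `timestamp_utc,depth_m`, epoch
#' seconds, full (`%.17g`) precision so a read/write cycle is bit-exact.
#'
#' @param record a [depth_record()].
#' @param path output path.
#' @export
write_depth_record <- function(record, path) {
  tsec <- as.numeric(record$t0) + (seq_len(record$n) - 1) * record$dt
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("timestamp_utc,depth_m", con)
  writeLines(sprintf("%.17g,%.17g", tsec, record$depth), con)
  invisible(path)
}

#' Fill gaps so the record is strictly uniform and complete
#'
#' @param record a [depth_record()].
#' @param gap_policy `"linear"` (interpolate across the gap), `"hold"`
#'   (repeat the last valid sample), or `"reject"` (error if any gap exceeds
#'   `max_gap`).
#' @param max_gap longest tolerated gap in seconds under `"reject"`
#'   (default 600 s).
#' @return a [depth_record()] with no missing samples; the gap log records
#'   every filled run. Idempotent: regularizing a complete record returns it
#'   unchanged.
#' @export
regularize <- function(record, gap_policy = c("linear", "hold", "reject"),
                       max_gap = 600) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(record, "depth_record"))
  depth <- record$depth
  if (!anyNA(depth)) return(record)
  log <- na_run_log(depth)
  if (gap_policy == "reject") {
    spans <- log$length * record$dt
    if (any(spans > max_gap)) {
      i <- which.max(spans)
      stop(sprintf("gap of %g s starting at sample %d exceeds max_gap = %g s",
                   spans[i], log$start_index[i], max_gap))
    }
  }
  if (is.na(depth[1L])) depth[1L] <- depth[which(!is.na(depth))[1L]]
  if (is.na(depth[length(depth)]))
    depth[length(depth)] <- depth[max(which(!is.na(depth)))]
  ok <- which(!is.na(depth))
  if (length(ok) < 2L) stop("record has fewer than 2 valid samples")
  if (gap_policy == "hold") {
    filled <- depth[ok][findInterval(seq_along(depth), ok)]
  } else {
    filled <- stats::approx(ok, depth[ok], xout = seq_along(depth),
                            method = "linear", rule = 2)$y
  }
  depth[is.na(depth)] <- filled[is.na(depth)]
  depth_record(depth, t0 = record$t0, dt = record$dt, gap_log = log)
}

#' Instantaneous vertical speed
#'
#' Central-difference rate of depth change dD/dt over a 2-sample span
#' (one-sided at the edges). Positive on descent, negative on ascent, by the
#' positive-down depth convention.
#'
#' @param record a regularized [depth_record()].
#' @return numeric vector of speeds (m/s), aligned to the record's samples.
#' @export
vertical_speed <- function(record) {
  stopifnot(inherits(record, "depth_record"))
  if (record$n < 3L) stop("need at least 3 samples for a speed estimate")
  if (anyNA(record$depth)) stop("regularize the record before computing speed")
  x <- record$depth
  n <- record$n
  dt <- record$dt
  v <- c(
    (x[2L] - x[1L]) / dt,
    (x[3:n] - x[1:(n - 2L)]) / (2 * dt),
    (x[n] - x[n - 1L]) / dt
  )
  v
}

#' Empirical depth quantiles
#'
#' Quantiles of the depth distribution (linear interpolation between order
#' statistics, `stats::quantile` type 7).
#'
#' @param record a [depth_record()].
#' @param probs probabilities in (0, 1].
#' @return named numeric vector of depths (m).
#' @export
depth_quantiles <- function(record, probs) {
  stopifnot(inherits(record, "depth_record"))
  if (any(probs <= 0 | probs > 1)) stop("probs must lie in (0, 1]")
  d <- record$depth[!is.na(record$depth)]
  if (length(d) == 0L) stop("empty record")
  stats::quantile(d, probs = probs, type = 7, names = TRUE)
}
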