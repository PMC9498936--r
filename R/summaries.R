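local_hour <- function(times, utc_offset_h = 0) {
  (as.numeric(times) / 3600 + utc_offset_h) %% 24
}

#' Diurnal percentile table of a windowed feature
#'
#' Assigns each window to an hour-of-day bin by its midpoint and reports
#' per-bin percentiles. The local clock is UTC plus a configurable offset
#' (default 0, which for the East Greenland record places solar culmination
#' near 13:29 local).
#'
#' @param times window start times (`POSIXct`).
#' @param values feature values, one per window.
#' @param bin_h bin width in hours (3 or 6 typically; must divide 24).
#' @param percentiles probabilities to report (default 0.05, 0.5, 0.75).
#' @param utc_offset_h local-clock offset from UTC in hours.
#' @param window_s window length (s) used to form midpoints (default 1800).
#' @return data frame with `bin_start_h`, one `P<...>` column per
#'   percentile, and `n`; bins tile 24 h, empty bins carry `NA`.
#' @export
diurnal_percentiles <- function(times, values, bin_h = 3,
                                percentiles = c(0.05, 0.5, 0.75),
                                utc_offset_h = 0, window_s = 1800) {
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  hrs <- local_hour(as.numeric(times) + window_s / 2, utc_offset_h)
  bin <- floor(hrs / bin_h) * bin_h
  bins <- seq(0, 24 - bin_h, by = bin_h)
  pc_names <- sprintf("P%g", 100 * percentiles)
  out <- data.frame(bin_start_h = bins)
  for (nm in pc_names) out[[nm]] <- NA_real_
  out$n <- 0L
  for (i in seq_along(bins)) {
    v <- values[bin == bins[i] & !is.na(values)]
    out$n[i] <- length(v)
    if (length(v) > 0)
      out[i, pc_names] <- as.list(stats::quantile(v, percentiles, names = FALSE))
  }
  out
}

#' Day vs night empirical CDFs of a feature
#'
#' Splits windows into a day period (06:00-18:00 local by default) and
#' night, and returns the two empirical cumulative distribution functions
#' together with the maximum vertical gap between them (a
#' Kolmogorov-style descriptive statistic; no test is attached).
#'
#' @inheritParams diurnal_percentiles
#' @param day_window 2-vector of local hours delimiting day.
#' @return list with `day` and `night` (ecdf functions), `max_gap`,
#'   `n_day`, `n_night`.
#' @export
day_night_ecdf <- function(times, values, day_window = c(6, 18),
                           utc_offset_h = 0, window_s = 1800) {
  hrs <- local_hour(as.numeric(times) + window_s / 2, utc_offset_h)
  is_day <- hrs >= day_window[1] & hrs < day_window[2]
  ok <- !is.na(values)
  vd <- values[is_day & ok]
  vn <- values[!is_day & ok]
  if (length(vd) == 0L || length(vn) == 0L)
    stop("day or night side is empty")
  Fd <- stats::ecdf(vd)
  Fn <- stats::ecdf(vn)
  grid <- sort(unique(c(vd, vn)))
  max_gap <- max(abs(Fd(grid) - Fn(grid)))
  list(day = Fd, night = Fn, max_gap = max_gap,
       n_day = length(vd), n_night = length(vn))
}

#' Behavioral time budget from labeled windows
#'
#' Fraction of assigned windows per semantic tag, optionally restricted to
#' windows whose membership confidence reaches `min_confidence`. Fractions
#' are over assigned (non-missing, retained) windows and sum to 1; a
#' grouped `bouts` aggregate (deep-bout + shallow-bout) is attached.
#'
#' @param labels data frame from [semantic_labels()].
#' @param min_confidence minimum soft-membership confidence, or `NULL` for
#'   all assigned windows.
#' @return data frame `tag`, `n`, `fraction`, with attributes `n_used`,
#'   `bouts_fraction` and `zero_denominator` flag.
#' @export
time_budget <- function(labels, min_confidence = NULL) {
  keep <- !is.na(labels$tag)
  if (!is.null(min_confidence))
    keep <- keep & labels$confidence >= min_confidence
  tags <- attr(labels, "tag_map")
  if (is.null(tags)) tags <- sort(unique(labels$tag[!is.na(labels$tag)]))
  n_used <- sum(keep)
  cnt <- vapply(tags, function(tg) sum(labels$tag[keep] == tg), numeric(1))
  frac <- if (n_used > 0) cnt / n_used else rep(NA_real_, length(tags))
  out <- data.frame(tag = tags, n = as.integer(cnt), fraction = frac,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_used") <- n_used
  attr(out, "zero_denominator") <- n_used == 0
  bouts <- c("deep-bout", "shallow-bout")
  attr(out, "bouts_fraction") <-
    if (n_used > 0 && all(bouts %in% tags)) sum(frac[out$tag %in% bouts])
    else NA_real_
  out
}

#' Tag composition of each hour-of-day bin
#'
#' Per diurnal bin, the fraction of assigned windows carrying each tag
#' (rows sum to 1; empty bins carry `NA`).
#'
#' @param labels data frame from [semantic_labels()] (POSIXct
#'   `window_start`).
#' @inheritParams diurnal_percentiles
#' @return data frame `bin_start_h`, one column per tag, and `n`.
#' @export
daypart_partition <- function(labels, bin_h = 3, utc_offset_h = 0,
                              window_s = 1800) {
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  keep <- !is.na(labels$tag)
  hrs <- local_hour(as.numeric(labels$window_start) + window_s / 2,
                    utc_offset_h)
  bin <- floor(hrs / bin_h) * bin_h
  bins <- seq(0, 24 - bin_h, by = bin_h)
  tags <- attr(labels, "tag_map")
  if (is.null(tags)) tags <- sort(unique(labels$tag[keep]))
  out <- data.frame(bin_start_h = bins)
  for (tg in tags) out[[tg]] <- NA_real_
  out$n <- 0L
  for (i in seq_along(bins)) {
    sel <- keep & bin == bins[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) {
      for (tg in tags) out[i, tg] <- sum(labels$tag[sel] == tg) / out$n[i]
    }
  }
  out
}

#' Cumulative count of windows carrying a tag
#'
#' Binary presence (1 when the window carries `tag`, else 0) accumulated
#' over window order; a change in the slope of this curve marks a change in
#' how often the behavior occurs.
#'
#' @param labels data frame from [semantic_labels()].
#' @param tag semantic tag to count.
#' @return data frame `window_start`, `cumulative`.
#' @export
cumulative_tag_count <- function(labels, tag) {
  known <- attr(labels, "tag_map")
  if (is.null(known)) known <- unique(labels$tag[!is.na(labels$tag)])
  if (!tag %in% known)
    stop(sprintf("unknown tag '%s' (known: %s)", tag,
                 paste(known, collapse = ", ")))
  present <- !is.na(labels$tag) & labels$tag == tag
  data.frame(window_start = labels$window_start,
             cumulative = cumsum(as.integer(present)))
}

#' Median of a feature before vs after a split date
#'
#' Medians over `[split - span, split)` and `[split, split + span)` with
#' their difference (after minus before) and a seeded bootstrap percentile
#' interval on the difference.
#'
#' @param times observation times (`POSIXct`).
#' @param values feature values.
#' @param split_time the split instant (`POSIXct` or coercible).
#' @param span_days half-window length in days (must be > 0).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf interval coverage (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `median_before`, `median_after`, `difference`,
#'   `ci` (2-vector), `n_before`, `n_after`, `truncated` flag.
#' @export
before_after_median <- function(times, values, split_time, span_days = 30,
                                n_boot = 1000, conf = 0.95, seed = 1) {
  if (span_days <= 0) stop("span_days must be positive")
  split_time <- as.POSIXct(split_time, tz = "UTC")
  t <- as.numeric(times)
  s <- as.numeric(split_time)
  span <- span_days * 86400
  ok <- !is.na(values)
  before <- values[ok & t >= s - span & t < s]
  after <- values[ok & t >= s & t < s + span]
  if (length(before) == 0L || length(after) == 0L)
    stop("before or after span is empty")
  truncated <- (s - span) < min(t) || (s + span) > max(t)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(after, replace = TRUE)) -
      stats::median(sample(before, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(median_before = stats::median(before),
       median_after = stats::median(after),
       difference = stats::median(after) - stats::median(before),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n_before = length(before), n_after = length(after),
       truncated = truncated)
}
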