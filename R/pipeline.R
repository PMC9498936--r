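#' Select embedding parameters from a depth record
#'
#' Delay: first local minimum of the auto-mutual-information curve (the
#' pointwise median over 6-h segments when the record covers at least two;
#' the global curve otherwise), with the first negative autocorrelation lag
#' as cross-check and fallback. Dimension: false-nearest-neighbor knee at
#' `R_T = 3` (smallest m with FNN below `fnn_threshold`).
#'
#' @param record a regularized [depth_record()].
#' @param max_lag_s largest delay-curve lag (s).
#' @param n_bins AMI histogram bins.
#' @param segment_s delay-curve segment length (s, default 6 h).
#' @param m_max largest dimension profiled.
#' @param R_T FNN distance-ratio threshold.
#' @param fnn_threshold FNN fraction declaring a dimension sufficient.
#' @param fnn_max_points stride cap for the FNN search.
#' @param lags optional explicit lag grid (samples).
#' @param fallback_m dimension used (and flagged) when no profiled
#'   dimension attains `fnn_threshold`, as happens for records whose
#'   observation noise and stochastic near-surface wander keep a floor
#'   under the FNN fraction; the default 3 is the physical prior for an
#'   animal moving in three spatial dimensions. Set `NA` to error instead.
#' @return list with `tau_s`, `m`, `m_flag` (`"fnn_threshold"` or
#'   `"fallback"`), `delay` (full [select_delay()] result), `fnn` profile,
#'   and the median curves.
#' @export
select_embedding <- function(record, max_lag_s = 1800, n_bins = 64,
                             segment_s = 21600, m_max = 5, R_T = 3,
                             fnn_threshold = 0.01, fnn_max_points = 1e4,
                             lags = NULL, fallback_m = 3) {
  stopifnot(inherits(record, "depth_record"))
  dt <- record$dt
  max_lag_s <- min(max_lag_s, (record$n - 1) * dt / 2)
  if (is.null(lags)) lags <- default_lag_grid(dt, max_lag_s)
  n_seg <- floor(record$n * dt / segment_s)
  if (n_seg >= 2) {
    ami <- segment_median_curve(record, segment_s, "ami", lags = lags,
                                n_bins = n_bins)
    acf <- segment_median_curve(record, segment_s, "acf", lags = lags)
  } else {
    ami <- auto_mutual_information(record$depth, lags, n_bins = n_bins)
    acf <- autocorrelation_curve(record$depth, max(lags))
  }
  delay <- select_delay(list(ami = ami, acf = acf), dt = dt)
  theiler <- 2L * delay$tau_samples
  prof <- false_nearest_fraction(record$depth, delay$tau_samples,
                                 m_range = 1:m_max, R_T = R_T,
                                 theiler = theiler,
                                 max_points = fnn_max_points)
  m <- tryCatch(select_dimension(prof, threshold = fnn_threshold),
                error = function(e) NA_integer_)
  m_flag <- "fnn_threshold"
  if (is.na(m)) {
    if (is.na(fallback_m)) {
      stop(sprintf("no dimension reaches FNN < %g and no fallback set",
                   fnn_threshold))
    }
    m <- as.integer(fallback_m)
    m_flag <- "fallback"
  }
  list(tau_s = delay$tau_s, m = m, m_flag = m_flag, delay = delay, fnn = prof,
       ami_curve = ami, acf_curve = acf)
}

#' Run the full dive-behavior decoding pipeline
#'
#' Regularize, select (or accept) embedding parameters, compute
#' sliding-window attractor invariants, decode behavioral states by
#' Gaussian-mixture clustering with AIC model selection, attach semantic
#' tags, and summarize diurnal structure and time budgets. When `out_dir`
#' is given, features, labels, the scan table, budgets and diurnal tables
#' are written as CSV, the fitted mixture as JSON, and every resolved
#' parameter is echoed into `manifest.json`; with `resume = TRUE` a
#' persisted feature table is reused instead of being recomputed.
#'
#' @param record a [depth_record()].
#' @param tau embedding delay in seconds, or `"auto"`.
#' @param m embedding dimension, or `"auto"`.
#' @param window_s,step_s sliding-window length and step (s).
#' @param k_range,structures,eps,n_init,seed mixture-scan settings (see
#'   [model_scan()]).
#' @param feature_transform `"none"` (default) to cluster the invariants
#'   on their raw scales, or `"log"` to log-transform the distance and
#'   energy features (both positive scale variables) before mixture
#'   fitting.
#' @param min_confidence confidence threshold for the filtered budget
#'   variant (default 0.9).
#' @param bin_h diurnal bin width (h).
#' @param utc_offset_h local-clock offset from UTC (h).
#' @param gap_policy passed to [regularize()].
#' @param out_dir optional output directory.
#' @param resume reuse persisted stage outputs when present.
#' @return list with `params`, `features`, `scan`, `fit`, `memberships`,
#'   `labels`, `budget`, `budget_high_confidence`, `daypart`, `diurnal`
#'   (per-feature percentile tables), and `manifest`.
#' @export
run_pipeline <- function(record, tau = "auto", m = "auto",
                         window_s = 1800, step_s = 600,
                         k_range = 1:6, structures = c("diag", "shared"),
                         eps = 0.25, n_init = 20, seed = 1,
                         feature_transform = c("none", "log"),
                         min_confidence = 0.9, bin_h = 3, utc_offset_h = 0,
                         gap_policy = "linear", out_dir = NULL,
                         resume = FALSE) {
  feature_transform <- match.arg(feature_transform)
  stopifnot(inherits(record, "depth_record"))
  record <- regularize(record, gap_policy = gap_policy)

  sel <- NULL
  if (identical(tau, "auto") || identical(m, "auto")) {
    sel <- select_embedding(record)
    if (identical(tau, "auto")) tau <- sel$tau_s
    if (identical(m, "auto")) m <- sel$m
  }
  tau <- as.numeric(tau)
  m <- as.integer(m)

  features_path <- if (!is.null(out_dir)) file.path(out_dir, "features.csv")
  features <- NULL
  if (resume && !is.null(features_path) && file.exists(features_path)) {
    features <- utils::read.csv(features_path, stringsAsFactors = FALSE)
    features$window_start <- as.POSIXct(features$window_start, tz = "UTC")
  }
  if (is.null(features)) {
    features <- sliding_features(record, tau, m, window_s = window_s,
                                 step_s = step_s)
  }

  fcols <- c("L_med", "Ek_med", "lyap", "dim")
  X <- as.matrix(features[, fcols])
  if (feature_transform == "log") {
    X[, "L_med"] <- log(X[, "L_med"])
    X[, "Ek_med"] <- log(X[, "Ek_med"])
  }
  ok <- stats::complete.cases(X)
  scan <- model_scan(X[ok, , drop = FALSE], k_range = k_range,
                     structures = structures, eps = eps, n_init = n_init,
                     seed = seed)
  fit <- scan$fit
  mem <- assign_memberships(fit, X)
  labels <- semantic_labels(fit, X, window_start = features$window_start,
                            memberships = mem)
  budget <- time_budget(labels)
  budget_hc <- time_budget(labels, min_confidence = min_confidence)
  daypart <- daypart_partition(labels, bin_h = bin_h,
                               utc_offset_h = utc_offset_h,
                               window_s = window_s)
  diurnal <- lapply(
    stats::setNames(c("Ek_med", "L_med", "lyap", "period_s"),
                    c("Ek_med", "L_med", "lyap", "period_s")),
    function(cl) diurnal_percentiles(features$window_start, features[[cl]],
                                     bin_h = bin_h,
                                     utc_offset_h = utc_offset_h,
                                     window_s = window_s))

  manifest <- list(
    n_samples = record$n, dt = record$dt,
    t0 = format(record$t0, "%Y-%m-%dT%H:%M:%SZ"),
    tau_s = tau, m = m,
    tau_method = if (!is.null(sel)) sel$delay$method else "user",
    m_flag = if (!is.null(sel)) sel$m_flag else "user",
    acf_first_negative_s = if (!is.null(sel)) sel$delay$acf_first_negative_s
                           else NA,
    fnn_profile = if (!is.null(sel)) sel$fnn else NULL,
    window_s = window_s, step_s = step_s, n_windows = nrow(features),
    global_dominant_period_s =
      attr(features, "params")$global_dominant_period_s,
    k = scan$selected_k, structure = scan$selected_structure,
    feature_transform = feature_transform,
    aic = fit$aic, eps = eps, n_init = n_init, seed = seed,
    min_confidence = min_confidence, bin_h = bin_h,
    utc_offset_h = utc_offset_h, gap_policy = gap_policy,
    tag_map = attr(labels, "tag_map")
  )

  out <- list(params = list(tau_s = tau, m = m, selection = sel),
              features = features, scan = scan, fit = fit,
              memberships = mem, labels = labels, budget = budget,
              budget_high_confidence = budget_hc, daypart = daypart,
              diurnal = diurnal, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fo <- features
    fo$window_start <- format(fo$window_start, "%Y-%m-%dT%H:%M:%SZ")
    utils::write.csv(fo, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    lo <- labels
    lo$window_start <- format(lo$window_start, "%Y-%m-%dT%H:%M:%SZ")
    utils::write.csv(lo, file.path(out_dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(scan$table, file.path(out_dir, "model_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(budget, file.path(out_dir, "time_budget.csv"),
                     row.names = FALSE)
    utils::write.csv(daypart, file.path(out_dir, "daypart_partition.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(weights = fit$weights, means = fit$means, vars = fit$vars,
           structure = fit$structure, k = fit$k,
           feature_names = fit$feature_names),
      file.path(out_dir, "mixture_fit.json"), digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
  }
  out
}
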