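#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Expectation-maximization for a k-component Gaussian mixture with either
#' per-component diagonal covariances (`"diag"`) or a single shared
#' diagonal covariance (`"shared"`). The best of `n_init` seeded random
#' restarts (means initialized at randomly chosen observations) is
#' returned; convergence is declared when the relative log-likelihood
#' improvement falls below `tol`. Deterministic given `seed`.
#'
#' Features enter on their raw scales by default, as the diagonal
#' covariances absorb per-feature scale; set `scale = TRUE` to z-score.
#'
#' @param features numeric matrix or data frame of complete-case rows
#'   (windows x features, e.g. `L_med`, `Ek_med`, `lyap`, `dim`).
#' @param k number of components (>= 1; at most `nrow/10`).
#' @param structure `"diag"` or `"shared"` covariance structure.
#' @param n_init number of random restarts (default 20).
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param scale z-score columns before fitting (default `FALSE`).
#' @return a `mixture_fit`: `weights`, `means` (k x d), `vars` (k x d),
#'   `loglik`, `aic` (`2p - 2 loglik`), `n_params`, `loglik_trace` (best
#'   restart), `structure`, `k`, `converged`, plus scaling metadata.
#' @export
fit_gmm <- function(features, k, structure = c("diag", "shared"),
                    n_init = 20, seed = 1, tol = 1e-6, max_iter = 500,
                    scale = FALSE) {
  structure <- match.arg(structure)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("features must be complete cases")
  n <- nrow(X); d <- ncol(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > 1L && k > n / 10) stop("k exceeds rows/10")
  center <- rep(0, d); scl <- rep(1, d)
  if (scale) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- em_once(X, k, structure, tol, max_iter)
    if (is.null(best) || (!is.null(fit) && fit$loglik > best$loglik)) best <- fit
    if (k == 1L) break  # closed form, restarts identical
  }
  if (is.null(best)) stop("EM failed to converge in every restart")
  p <- if (structure == "diag") (k - 1) + k * d + k * d else (k - 1) + k * d + d
  structure(list(
    weights = best$weights, means = best$means, vars = best$vars,
    loglik = best$loglik, n_params = p, aic = 2 * p - 2 * best$loglik,
    loglik_trace = best$trace, structure = structure, k = k,
    converged = best$converged, n_iter = length(best$trace),
    feature_names = colnames(features),
    center = center, scl = scl, scaled = scale
  ), class = "mixture_fit")
}

# kmeans++-style seeding: spread initial means by distance-weighted sampling
seed_means <- function(X, k) {
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(X, 2, sds, "/")
  centers <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(Z, 2, Z[centers, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers <- c(centers, sample.int(n, 1, prob = p))
      d2 <- pmin(d2, rowSums(sweep(Z, 2, Z[centers[j], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

em_once <- function(X, k, structure, tol, max_iter) {
  n <- nrow(X); d <- ncol(X)
  var_floor <- pmax(apply(X, 2, stats::var), .Machine$double.eps) * 1e-8 + 1e-12
  means <- seed_means(X, k)
  gvar <- apply(X, 2, stats::var)
  gvar[gvar == 0] <- 1
  vars <- matrix(gvar, nrow = k, ncol = d, byrow = TRUE)
  weights <- rep(1 / k, k)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      lp[, j] <- log(weights[j]) -
        0.5 * rowSums(sweep(sweep(X, 2, means[j, ])^2, 2, vars[j, ], "/")) -
        0.5 * sum(log(2 * pi * vars[j, ]))
    }
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) {
      # dead component: reseed it at the point with the lowest likelihood
      for (j in which(nk < 1e-10)) {
        means[j, ] <- X[which.min(lse), ]
        vars[j, ] <- gvar
      }
      next
    }
    weights <- nk / n
    means <- (t(resp) %*% X) / nk
    for (j in seq_len(k)) {
      dev2 <- sweep(X, 2, means[j, ])^2
      vars[j, ] <- colSums(resp[, j] * dev2) / nk[j]
    }
    if (structure == "shared") {
      pooled <- colSums(vars * nk) / n
      vars <- matrix(pooled, nrow = k, ncol = d, byrow = TRUE)
    }
    vars <- pmax(vars, matrix(var_floor, k, d, byrow = TRUE))
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged && max_iter > 1L) return(NULL)
  # reject degenerate solutions whose likelihood rests on a component
  # supporting fewer points than it has free mean/variance parameters
  if (any(weights * n < d + 1)) return(NULL)
  list(weights = weights, means = means, vars = vars,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d (%s covariance), loglik = %.2f, AIC = %.2f\n",
              x$k, x$structure, x$loglik, x$aic))
  invisible(x)
}

#' Scan mixture sizes and covariance structures by AIC
#'
#' Fits every `(k, structure)` combination and selects the component count
#' per structure by an improvement-stall rule: scanning k upward, stop at
#' the first k whose AIC improvement over k-1 is non-positive or falls
#' below `eps` times the largest improvement seen so far, and select k-1
#' ("no obvious further improvement"). An absolute threshold on AIC would
#' not survive rescaling of the features -- the log-density, and with it
#' |AIC|, shifts by an arbitrary constant -- whereas improvement ratios
#' compare like with like. If the improvements never stall, the largest
#' scanned k is returned with a flag. The reported structure is the one
#' with the lower AIC at its selected k. Fit errors are recorded and the
#' scan continues.
#'
#' @param features complete-case feature matrix/data frame.
#' @param k_range integer vector of component counts (default 1:6).
#' @param structures covariance structures to scan.
#' @param eps stall threshold as a fraction of the largest AIC improvement
#'   seen so far (default 0.25).
#' @inheritParams fit_gmm
#' @return list with `table` (data frame `k`, `structure`, `loglik`, `aic`,
#'   `error`), `selected_k`, `selected_structure`, `fit` (refit at the
#'   selection), and `per_structure` selections.
#' @export
model_scan <- function(features, k_range = 1:6,
                       structures = c("diag", "shared"), eps = 0.25,
                       n_init = 20, seed = 1, scale = FALSE) {
  k_range <- sort(as.integer(k_range))
  rows <- list()
  fits <- list()
  for (st in structures) {
    for (k in k_range) {
      f <- tryCatch(fit_gmm(features, k, structure = st, n_init = n_init,
                            seed = seed, scale = scale),
                    error = function(e) e)
      if (inherits(f, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, structure = st, loglik = NA_real_, aic = NA_real_,
          error = conditionMessage(f))
      } else {
        fits[[paste(st, k)]] <- f
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, structure = st, loglik = f$loglik, aic = f$aic, error = "")
      }
    }
  }
  tab <- do.call(rbind, rows)
  per_structure <- list()
  for (st in structures) {
    sub <- tab[tab$structure == st & is.finite(tab$aic), ]
    sub <- sub[order(sub$k), ]
    if (nrow(sub) == 0L) next
    sel <- sub$k[nrow(sub)]
    flag <- "no_stall"
    if (nrow(sub) >= 2L) {
      impr <- -diff(sub$aic)
      for (i in seq_along(impr)) {
        thr <- if (i == 1L) 0 else eps * max(impr[seq_len(i - 1L)])
        if (impr[i] <= max(thr, 0)) {
          sel <- sub$k[i]
          flag <- "ok"
          break
        }
      }
    }
    per_structure[[st]] <- list(k = sel, flag = flag,
                                aic = sub$aic[sub$k == sel])
  }
  if (length(per_structure) == 0L) stop("every mixture fit failed")
  aics <- vapply(per_structure, function(z) z$aic, numeric(1))
  best_st <- names(per_structure)[which.min(aics)]
  best_k <- per_structure[[best_st]]$k
  list(table = tab, selected_k = best_k, selected_structure = best_st,
       fit = fits[[paste(best_st, best_k)]], per_structure = per_structure)
}

#' Soft (posterior) membership of windows in mixture components
#'
#' Exact posterior responsibilities under the fitted mixture; hard labels
#' are the argmax (ties to the lower component index) and the confidence is
#' the maximum posterior. Rows with missing features are flagged
#' unassigned (`NA` label, zero confidence).
#'
#' @param fit a `mixture_fit`.
#' @param features feature rows to score (may contain `NA` rows).
#' @return a `memberships` list: `posterior` (windows x k), `hard`
#'   (integer labels), `confidence`.
#' @export
assign_memberships <- function(fit, features) {
  stopifnot(inherits(fit, "mixture_fit"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (fit$scaled)
    X <- sweep(sweep(X, 2, fit$center), 2, fit$scl, "/")
  n <- nrow(X); k <- fit$k
  post <- matrix(NA_real_, n, k)
  ok <- stats::complete.cases(X)
  if (any(ok)) {
    Xo <- X[ok, , drop = FALSE]
    lp <- matrix(0, sum(ok), k)
    for (j in seq_len(k)) {
      lp[, j] <- log(fit$weights[j]) -
        0.5 * rowSums(sweep(sweep(Xo, 2, fit$means[j, ])^2, 2,
                            fit$vars[j, ], "/")) -
        0.5 * sum(log(2 * pi * fit$vars[j, ]))
    }
    mx <- apply(lp, 1, max)
    post[ok, ] <- exp(lp - (mx + log(rowSums(exp(lp - mx)))))
  }
  hard <- rep(NA_integer_, n)
  conf <- rep(0, n)
  if (any(ok)) {
    hard[ok] <- max.col(post[ok, , drop = FALSE], ties.method = "first")
    conf[ok] <- post[cbind(which(ok), hard[ok])]
  }
  structure(list(posterior = post, hard = hard, confidence = conf,
                 unassigned = which(!ok)),
            class = "memberships")
}

#' Behavioral semantic tags for mixture components
#'
#' Orders components by their mean Euclidean distance `L` (descending):
#' the largest-L component is tagged `deep-bout`, the next `shallow-bout`,
#' the smallest-L `near-surface-shallow`, and the remaining component(s)
#' `intermediate`. For k other than 4 the tags are `cluster-1..k` in
#' descending-L order. Ties in mean L (within `tol`) fall back to mean
#' `E_k` ordering and are flagged.
#'
#' @param fit a `mixture_fit` whose features include `L_med` (and `Ek_med`
#'   for the tie fallback), or any fit when `l_col`/`ek_col` name the
#'   columns.
#' @param features the feature rows to label.
#' @param window_start optional vector of window start times carried into
#'   the output.
#' @param memberships optional precomputed [assign_memberships()] result.
#' @param l_col,ek_col names of the distance and energy feature columns.
#' @param tol tie tolerance on mean L (default 1e-6 relative).
#' @return data frame `window_start`, `cluster`, `confidence`, `tag`, with
#'   attributes `tag_map` (component -> tag) and `tie_flag`.
#' @export
semantic_labels <- function(fit, features, window_start = NULL,
                            memberships = NULL, l_col = "L_med",
                            ek_col = "Ek_med", tol = 1e-6) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(memberships)) memberships <- assign_memberships(fit, features)
  cols <- fit$feature_names
  li <- match(l_col, cols)
  if (is.na(li)) stop(sprintf("fit has no feature column '%s'", l_col))
  meanL <- fit$means[, li] * fit$scl[li] + fit$center[li]
  tie_flag <- FALSE
  o <- order(-meanL)
  if (anyDuplicated(signif(meanL, 8)) ||
      any(abs(diff(sort(meanL))) <= tol * max(abs(meanL)))) {
    ei <- match(ek_col, cols)
    if (!is.na(ei)) {
      meanE <- fit$means[, ei]
      o <- order(-meanL, -meanE)
      tie_flag <- TRUE
    }
  }
  k <- fit$k
  tags <- if (k == 4L) {
    c("deep-bout", "shallow-bout", "intermediate", "near-surface-shallow")
  } else {
    sprintf("cluster-%d", seq_len(k))
  }
  tag_map <- character(k)
  tag_map[o] <- tags
  n <- length(memberships$hard)
  if (is.null(window_start)) window_start <- seq_len(n)
  out <- data.frame(
    window_start = window_start,
    cluster = memberships$hard,
    confidence = memberships$confidence,
    tag = ifelse(is.na(memberships$hard), NA_character_,
                 tag_map[memberships$hard]),
    stringsAsFactors = FALSE
  )
  attr(out, "tag_map") <- tag_map
  attr(out, "tie_flag") <- tie_flag
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (1 = identical partitions, 0 = expected agreement at random).
#'
#' @param a,b label vectors of equal length (NAs dropped pairwise).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}
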