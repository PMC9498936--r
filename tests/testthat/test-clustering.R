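two_blob_data <- function(seed, n = 200, sep = 8) {
  set.seed(seed)
  rbind(matrix(stats::rnorm(n * 2), ncol = 2),
        matrix(stats::rnorm(n * 2, mean = sep), ncol = 2))
}

test_that("a one-component fit reduces to the sample moments", {
  set.seed(41)
  X <- matrix(stats::rnorm(300, sd = 2), ncol = 3)
  fit <- fit_gmm(X, k = 1)
  expect_equal(as.numeric(fit$means), colMeans(X))
  mle_var <- apply(X, 2, function(v) mean((v - mean(v))^2))
  expect_equal(as.numeric(fit$vars), mle_var, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("EM is deterministic, monotone, and finds separated centers", {
  X <- two_blob_data(42)
  f1 <- fit_gmm(X, 2, seed = 7)
  f2 <- fit_gmm(X, 2, seed = 7)
  expect_identical(f1$aic, f2$aic)
  expect_identical(f1$means, f2$means)
  # loglik trace never decreases
  expect_true(all(diff(f1$loglik_trace) > -1e-6))
  expect_equal(sum(f1$weights), 1, tolerance = 1e-9)

  hits <- 0L
  for (s in 1:10) {
    X <- two_blob_data(500 + s, n = 800)
    f <- fit_gmm(X, 2, n_init = 10, seed = s)
    o <- order(f$means[, 1])
    err <- max(abs(f$means[o, ] - rbind(c(0, 0), c(8, 8))))
    if (err < 0.1 * 1) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("shared covariances cost likelihood on heteroscedastic data", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    X <- rbind(matrix(stats::rnorm(300, sd = 0.5), ncol = 2),
               matrix(stats::rnorm(300, mean = 6, sd = 3), ncol = 2))
    a_diag <- fit_gmm(X, 2, "diag", seed = s)$aic
    a_shared <- fit_gmm(X, 2, "shared", seed = s)$aic
    if (a_shared >= a_diag) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("component count guardrails hold", {
  X <- two_blob_data(43, n = 20)
  expect_error(fit_gmm(X, 5), "rows/10")
  expect_error(fit_gmm(X, 0), "at least 1")
  expect_error(fit_gmm(rbind(X, c(NA, 1)), 2), "complete")
})

test_that("the scan prefers one component for a single blob", {
  # at small n the two-component MLE is legitimately close enough for AIC
  # to waver; 1000 points give the penalty room to bite
  hits <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    X <- matrix(stats::rnorm(2000), ncol = 2)
    sc <- model_scan(X, k_range = 1:3, n_init = 10, seed = s)
    if (sc$selected_k == 1) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("posterior memberships are exact and handle missing rows", {
  X <- two_blob_data(44)
  fit <- fit_gmm(X, 2, seed = 1)
  mem <- assign_memberships(fit, X)
  expect_true(all(abs(rowSums(mem$posterior) - 1) < 1e-9))
  # a point at a component mean of a well-separated fit is unambiguous
  at_mean <- assign_memberships(fit, fit$means)
  expect_true(all(at_mean$confidence > 0.99))
  # symmetric equidistant point splits 50/50
  sym <- structure(list(weights = c(0.5, 0.5),
                        means = rbind(c(-1, 0), c(1, 0)),
                        vars = rbind(c(1, 1), c(1, 1)),
                        loglik = 0, n_params = 9, aic = 0,
                        loglik_trace = 0, structure = "diag", k = 2L,
                        converged = TRUE, n_iter = 1L,
                        feature_names = c("a", "b"),
                        center = c(0, 0), scl = c(1, 1), scaled = FALSE),
                   class = "mixture_fit")
  eq <- assign_memberships(sym, matrix(c(0, 5), 1))
  expect_equal(as.numeric(eq$posterior), c(0.5, 0.5))
  expect_equal(eq$hard, 1L)  # tie goes to the lower index

  withna <- rbind(X[1:3, ], c(NA, 2))
  memna <- assign_memberships(fit, withna)
  expect_equal(memna$unassigned, 4L)
  expect_true(is.na(memna$hard[4]))
})

test_that("semantic tags follow the distance ordering rule", {
  mk_fit <- function(meanL) {
    k <- length(meanL)
    structure(list(weights = rep(1 / k, k),
                   means = cbind(meanL, seq_len(k)),
                   vars = matrix(1, k, 2),
                   loglik = 0, n_params = 1, aic = 0, loglik_trace = 0,
                   structure = "diag", k = k, converged = TRUE, n_iter = 1L,
                   feature_names = c("L_med", "Ek_med"),
                   center = c(0, 0), scl = c(1, 1), scaled = FALSE),
              class = "mixture_fit")
  }
  fit <- mk_fit(c(500, 80, 5, 30))
  X <- fit$means
  lab <- semantic_labels(fit, X)
  expect_equal(attr(lab, "tag_map"),
               c("deep-bout", "shallow-bout", "near-surface-shallow",
                 "intermediate"))
  # permuting component order leaves the semantic tags attached to the
  # same physical clusters
  perm <- c(3, 1, 4, 2)
  fitp <- mk_fit(c(500, 80, 5, 30)[perm])
  labp <- semantic_labels(fitp, X[perm, , drop = FALSE])
  expect_equal(attr(labp, "tag_map"), attr(lab, "tag_map")[perm])
})

test_that("adjusted Rand agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(45)
  for (i in 1:5) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10 %% 2, (1:10 %% 2) + 5), 1)
})

test_that("our EM matches an independent mixture fitter on easy data", {
  skip_if_not_installed("mclust")
  X <- two_blob_data(46)
  fit <- fit_gmm(X, 2, "diag", n_init = 20, seed = 1)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
})
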