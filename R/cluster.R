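#' Cluster paired-timepoint CCFs with a 2-D Gaussian mixture
#'
#' Approximates Dirichlet-process subclonal reconstruction with finite
#' Gaussian mixtures: (early, late) CCF pairs are fit with shared
#' spherical-variance mixtures for k = 1..\code{k_max} by EM (kmeans
#' initialization, \code{n_restarts} restarts per k), and k is selected
#' by BIC. Variants absent at one timepoint should enter with CCF 0
#' there: appearing and vanishing clusters are precisely the signal the
#' downstream evolution classifier uses.
#'
#' @param ccf_early,ccf_late aligned per-variant CCFs (same length).
#' @param k_max maximum number of clusters (default 6).
#' @param n_restarts EM restarts per k (default 10).
#' @param min_variants below this many variants a degraded single-cluster
#'   solution is returned with a warning (default 10).
#' @return a \code{ccf_cluster_solution}: list with \code{clusters}
#'   (data.frame: \code{mean_ccf_early}, \code{mean_ccf_late},
#'   \code{weight}, \code{n_variants}), \code{assignments},
#'   \code{k}, \code{model_score} (BIC, lower is better),
#'   \code{loglik}, \code{degraded}.
#' @export
cluster_pair <- function(ccf_early, ccf_late, k_max = 6L, n_restarts = 10L,
                         min_variants = 10L) {
  if (length(ccf_early) != length(ccf_late)) {
    stop("ccf_early and ccf_late must be aligned (same length)")
  }
  n <- length(ccf_early)
  if (n < 2L) stop("clustering needs at least 2 shared variants")
  x <- cbind(early = ccf_early, late = ccf_late)
  if (n < min_variants) {
    warning("fewer than ", min_variants,
            " variants; returning degraded single-cluster solution")
    return(single_cluster_solution(x, degraded = TRUE))
  }
  best <- NULL
  for (k in seq_len(min(k_max, n))) {
    fit <- gmm2d_fit(x, k, n_restarts = n_restarts)
    if (is.null(fit)) next
    n_par <- (k - 1) + 2 * k + 1  # weights + means + shared variance
    bic <- -2 * fit$loglik + n_par * log(n)
    if (is.null(best) || bic < best$bic) {
      best <- c(fit, list(bic = bic, k = k))
    }
  }
  cl <- best$assignments
  tab <- tabulate(cl, nbins = best$k)
  clusters <- data.frame(
    mean_ccf_early = best$means[, 1],
    mean_ccf_late = best$means[, 2],
    weight = best$weights,
    n_variants = tab)
  structure(list(clusters = clusters, assignments = cl, k = best$k,
                 model_score = best$bic, loglik = best$loglik,
                 degraded = FALSE),
            class = "ccf_cluster_solution")
}

single_cluster_solution <- function(x, degraded = FALSE) {
  mu <- colMeans(x)
  structure(list(
    clusters = data.frame(mean_ccf_early = mu[1], mean_ccf_late = mu[2],
                          weight = 1, n_variants = nrow(x)),
    assignments = rep(1L, nrow(x)), k = 1L,
    model_score = NA_real_, loglik = NA_real_, degraded = degraded),
    class = "ccf_cluster_solution")
}

# Shared spherical-variance Gaussian mixture EM in 2-D.
# Returns NULL when every restart degenerates.
gmm2d_fit <- function(x, k, n_restarts = 10L, tol = 1e-6,
                      max_iter = 300L, var_floor = 1e-6) {
  n <- nrow(x)
  best <- NULL
  if (k == 1L) n_restarts <- 1L  # single-component fit is deterministic
  for (r in seq_len(n_restarts)) {
    centers <- if (k == 1L) {
      matrix(colMeans(x), nrow = 1)
    } else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = k, nstart = 1)),
        error = function(e) NULL)
      if (is.null(km)) {
        x[sample.int(n, k), , drop = FALSE]
      } else {
        km$centers
      }
    }
    fit <- gmm2d_em(x, centers, tol = tol, max_iter = max_iter,
                    var_floor = var_floor)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

gmm2d_em <- function(x, centers, tol = 1e-6, max_iter = 300L,
                     var_floor = 1e-6) {
  n <- nrow(x)
  k <- nrow(centers)
  mu <- centers
  w <- rep(1 / k, k)
  sigma2 <- max(mean(apply(x, 2, stats::var)), var_floor)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step: log densities, n x k
    logd <- vapply(seq_len(k), function(j) {
      d2 <- (x[, 1] - mu[j, 1])^2 + (x[, 2] - mu[j, 2])^2
      log(w[j]) - log(2 * pi * sigma2) - d2 / (2 * sigma2)
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- logd[cbind(seq_len(n), max.col(logd))]
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    # M-step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)  # empty component
    w <- nk / n
    mu <- t(resp) %*% x / nk
    d2 <- sapply(seq_len(k), function(j) {
      (x[, 1] - mu[j, 1])^2 + (x[, 2] - mu[j, 2])^2
    })
    d2 <- matrix(d2, nrow = n)
    sigma2 <- max(sum(resp * d2) / (2 * n), var_floor)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, means = mu, weights = w, sigma2 = sigma2,
       assignments = max.col(resp))
}

#' @export
print.ccf_cluster_solution <- function(x, ...) {
  cat("CCF cluster solution: k =", x$k,
      if (x$degraded) "(degraded)" else
        paste0("(BIC = ", round(x$model_score, 1), ")"), "\n")
  df <- x$clusters
  df[] <- lapply(df, function(v) if (is.numeric(v)) round(v, 3) else v)
  print.data.frame(df, row.names = TRUE)
  invisible(x)
}
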