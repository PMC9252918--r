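#' Maximum-likelihood signature refitting
#'
#' Fits a catalog as a convex mixture of known signature profiles by
#' expectation-maximization on the multinomial likelihood: the catalog is
#' modeled as counts drawn from \eqn{p_c = \sum_s w_s P_{sc}} and the
#' mixture weights \eqn{w} are estimated to convergence (absolute
#' log-likelihood change below \code{tol}). A parsimony pass then removes,
#' by backward elimination, any signature whose removal degrades the
#' cosine similarity between the catalog and its reconstruction by less
#' than \code{epsilon}, and refits; signatures named in \code{protect}
#' (by default the melphalan signature, whose presence is judged by its
#' bootstrap CI instead) are never pruned. Converged weights below
#' \code{zero_tol} are truncated to exact zeros and the vector
#' renormalized, so absent signatures report 0 rather than EM dust.
#'
#' @param catalog an \code{sbs_catalog} (or named 96-vector of counts).
#' @param ref a \code{signature_reference}.
#' @param parsimony run the backward-elimination pruning pass.
#' @param epsilon cosine-similarity drop below which a signature is
#'   considered dispensable (default 0.01).
#' @param protect signature names never pruned (default "SBS-MM1" when
#'   present in the reference).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param zero_tol weights below this are truncated to 0 after
#'   convergence.
#' @return named numeric vector of weights summing to 1, with attributes
#'   \code{loglik}, \code{cosine} (reconstruction cosine similarity) and
#'   \code{n_mutations}.
#' @export
fit_exposures <- function(catalog, ref, parsimony = TRUE, epsilon = 0.01,
                          protect = intersect("SBS-MM1", rownames(ref)),
                          tol = 1e-8, max_iter = 10000L, zero_tol = 1e-4) {
  counts <- align_catalog(catalog, ref)
  if (sum(counts) < 1) {
    stop("empty catalog: signature fitting needs at least 1 mutation ",
         "(and is unreliable below ~50)")
  }
  if (nrow(ref) == 0L) stop("signature reference is empty")
  fit <- em_refit(matrix(counts, nrow = 1), ref, tol = tol,
                  max_iter = max_iter)
  w <- fit$weights[1, ]
  active <- rownames(ref)
  if (parsimony && nrow(ref) > 1L) {
    base_cos <- cosine_sim(counts, drop(w %*% ref))
    repeat {
      candidates <- setdiff(active, protect)
      if (length(candidates) == 0L || length(active) == 1L) break
      best <- NULL
      for (s in candidates) {
        trial <- setdiff(active, s)
        fw <- em_refit(matrix(counts, nrow = 1),
                       ref[trial, , drop = FALSE],
                       tol = tol, max_iter = max_iter)$weights[1, ]
        cs <- cosine_sim(counts, drop(fw %*% ref[trial, , drop = FALSE]))
        if (is.null(best) || cs > best$cos) {
          best <- list(sig = s, cos = cs, w = fw, active = trial)
        }
      }
      if (base_cos - best$cos < epsilon) {
        active <- best$active
        w <- stats::setNames(numeric(nrow(ref)), rownames(ref))
        w[active] <- best$w
        base_cos <- cosine_sim(counts, drop(w[active] %*%
                                              ref[active, , drop = FALSE]))
      } else {
        break
      }
    }
  }
  w[w < zero_tol] <- 0
  w <- w / sum(w)
  recon <- drop(w %*% ref)
  structure(w,
            loglik = multinom_loglik(counts, recon),
            cosine = cosine_sim(counts, recon),
            n_mutations = sum(counts))
}

# Vectorized multinomial-mixture EM over B catalogs sharing one reference.
# counts: B x 96, ref: S x 96 (rows sum to 1). Returns B x S weights.
# The EM update is
#   w'_{bs} = (1/N_b) * sum_c n_{bc} w_{bs} P_{sc} / sum_s' w_{bs'} P_{s'c}
# Each iteration updates only the catalogs whose log-likelihood is still
# moving by more than tol (active-set), so large bootstrap batches finish
# as soon as their members converge.
em_refit <- function(counts, ref, tol = 1e-8, max_iter = 10000L,
                     trace = FALSE) {
  B <- nrow(counts)
  S <- nrow(ref)
  P <- unclass(ref)
  W <- matrix(1 / S, nrow = B, ncol = S,
              dimnames = list(NULL, rownames(ref)))
  N <- rowSums(counts)
  ll_old <- rep(-Inf, B)
  active <- seq_len(B)
  ll_trace <- if (trace) vector("list", B) else NULL
  iters <- 0L
  while (length(active) > 0L && iters < max_iter) {
    iters <- iters + 1L
    Wa <- W[active, , drop = FALSE]
    Na <- counts[active, , drop = FALSE]
    M <- Wa %*% P
    M[M < 1e-300] <- 1e-300
    Wa_new <- Wa * ((Na / M) %*% t(P)) / N[active]
    Wa_new <- Wa_new / rowSums(Wa_new)
    M_new <- Wa_new %*% P
    M_new[M_new < 1e-300] <- 1e-300
    ll_new <- rowSums(Na * log(M_new))
    W[active, ] <- Wa_new
    if (trace) {
      for (i in seq_along(active)) {
        ll_trace[[active[i]]] <- c(ll_trace[[active[i]]], ll_new[i])
      }
    }
    converged <- abs(ll_new - ll_old[active]) < tol
    ll_old[active] <- ll_new
    active <- active[!converged]
  }
  list(weights = W, loglik = ll_old, iterations = iters,
       ll_trace = ll_trace)
}

multinom_loglik <- function(counts, probs) {
  probs[probs < 1e-300] <- 1e-300
  sum(counts * log(probs))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

align_catalog <- function(catalog, ref) {
  channels <- colnames(ref)
  x <- as.numeric(catalog)
  if (length(x) != 96L) stop("catalog must have 96 channels")
  if (!is.null(names(catalog)) &&
      !identical(names(catalog), channels)) {
    if (!setequal(names(catalog), channels)) {
      stop("catalog channel order does not match the reference")
    }
    x <- x[match(channels, names(catalog))]
  }
  stats::setNames(x, channels)
}

#' Signature exposures with bootstrap confidence intervals
#'
#' Point-fits the catalog (with parsimony pruning), then resamples the
#' catalog's mutations with replacement (multinomial draws of the same
#' total from the observed channel frequencies), refits each replicate on
#' the retained signatures, and reports percentile confidence intervals
#' at the requested level. A signature is called present when the lower
#' CI bound is strictly positive. Within each bootstrap replicate a
#' signature-wise support check is applied: the replicate is refit
#' without the signature and, when the log-likelihood gain from keeping
#' it is below \code{llr_tol} (default 1.92, the 95\% point of a
#' half-chi-squared with 1 df), the replicate's weight for that
#' signature is recorded as 0. Without this replicate-level zeroing
#' every lower bound would be positive by construction, since interior
#' EM weights never reach exactly zero.
#'
#' @inheritParams fit_exposures
#' @param n_bootstrap number of bootstrap replicates (default 1000).
#' @param level CI level in (0,1) (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @param llr_tol per-replicate log-likelihood-ratio threshold below
#'   which a signature's replicate weight is zeroed (default 1.92).
#' @return a \code{signature_exposure} data.frame with columns
#'   \code{signature}, \code{weight}, \code{ci_low}, \code{ci_high},
#'   \code{present}, and attributes \code{sample_id}, \code{n_mutations},
#'   \code{n_bootstrap}, \code{level}.
#' @export
bootstrap_ci <- function(catalog, ref, n_bootstrap = 1000L, level = 0.95,
                         seed = NULL, parsimony = TRUE, epsilon = 0.01,
                         protect = intersect("SBS-MM1", rownames(ref)),
                         tol = 1e-8, max_iter = 10000L, zero_tol = 1e-4,
                         llr_tol = 1.92) {
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  counts <- align_catalog(catalog, ref)
  point <- fit_exposures(catalog, ref, parsimony = parsimony,
                         epsilon = epsilon, protect = protect, tol = tol,
                         max_iter = max_iter, zero_tol = zero_tol)
  retained <- union(names(point)[point > 0], protect)
  retained <- rownames(ref)[rownames(ref) %in% retained]
  subref <- ref[retained, , drop = FALSE]
  N <- sum(counts)
  boots <- t(stats::rmultinom(n_bootstrap, size = N, prob = counts / N))
  fit_full <- em_refit(boots, subref, tol = tol, max_iter = max_iter)
  W <- fit_full$weights
  if (length(retained) > 1L) {
    # replicate-level signature-wise support check (see above)
    for (s in retained) {
      others <- setdiff(retained, s)
      fit_s <- em_refit(boots, subref[others, , drop = FALSE],
                        tol = tol, max_iter = max_iter)
      unsupported <- (fit_full$loglik - fit_s$loglik) < llr_tol
      W[unsupported, s] <- 0
    }
  }
  W[W < zero_tol] <- 0
  W <- W / rowSums(W)
  alpha <- (1 - level) / 2
  full <- matrix(0, nrow = n_bootstrap, ncol = nrow(ref),
                 dimnames = list(NULL, rownames(ref)))
  full[, retained] <- W
  ci <- apply(full, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  res <- data.frame(
    signature = rownames(ref),
    weight = as.numeric(point),
    ci_low = ci[1, ],
    ci_high = ci[2, ],
    present = ci[1, ] > 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("signature_exposure", "data.frame"),
            sample_id = attr(catalog, "sample_id"),
            n_mutations = N, n_bootstrap = n_bootstrap, level = level)
}

row_cosine <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  ifelse(den == 0, 0, num / den)
}

#' Pooled (group-level) signature fit
#'
#' Element-wise sums a list of catalogs into one pooled catalog and runs
#' [bootstrap_ci()] on it. Pooling is how exposure groups (e.g. high-dose
#' melphalan vs low-dose vs none) are assessed jointly: a signature
#' carried by only a few members is diluted and may no longer be called
#' present at the group level.
#'
#' @param catalogs list of \code{sbs_catalog}s (same channel order).
#' @param ref a \code{signature_reference}.
#' @param group_label label stored on the result.
#' @param ... passed to [bootstrap_ci()].
#' @return a \code{signature_exposure} for the pooled catalog.
#' @export
group_fit <- function(catalogs, ref, group_label = NA_character_, ...) {
  if (length(catalogs) < 1L) stop("need at least one catalog")
  channels <- sbs96_channels()
  mats <- lapply(catalogs, function(cc) {
    if (!identical(names(cc), channels)) {
      stop("mixed channel orders across catalogs")
    }
    as.integer(cc)
  })
  pooled <- as_catalog(Reduce(`+`, mats), sample_id = group_label)
  bootstrap_ci(pooled, ref, ...)
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat("Signature exposures",
      if (!is.na(attr(x, "sample_id"))) paste0("[", attr(x, "sample_id"), "]"),
      "- n =", attr(x, "n_mutations"), "mutations,",
      attr(x, "n_bootstrap"), "bootstraps,",
      paste0(100 * attr(x, "level"), "% CI"), "\n")
  df <- as.data.frame(x)
  df$weight <- round(df$weight, 4)
  df$ci_low <- round(df$ci_low, 4)
  df$ci_high <- round(df$ci_high, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
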