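#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximization for a k-component univariate Gaussian mixture
#' with per-component variance (the 1-D case of a diagonal covariance
#' model). Initialization is deterministic by default: component means at
#' the k evenly-spaced sample quantiles, equal weights, pooled variance.
#' With `n_start > 1`, additional starts draw means at random from the data
#' (seeded) and the best final log-likelihood wins.
#'
#' Convergence is declared when the relative log-likelihood change drops
#' below `tol` before `max_iter` iterations (default 140). If any component
#' variance collapses to the floor, the fit is flagged non-converged —
#' mirroring how a 3-component model can fail on bimodal PLV data.
#'
#' @param plvs Numeric observations (PLVs).
#' @param k Number of components, >= 1.
#' @param max_iter Maximum EM iterations (default 140).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor Variance floor in squared PLV units.
#' @param n_start Number of EM starts (first is the quantile start).
#' @param seed Seed for the random restarts.
#' @return An object of class `mixture_fit`: `k`, `weights`, `means`,
#'   `variances`, `loglik`, `loglik_trace`, `aic` (`2p - 2 lnL` with
#'   `p = 3k - 1`), `converged`, `responsibilities`, `n`.
#' @export
fit_gmm <- function(plvs, k, max_iter = 140, tol = 1e-6, var_floor = 1e-6,
                    n_start = 1, seed = NULL) {
  x <- as.numeric(plvs)
  n <- length(x)
  if (k <= 0) stop("k must be a positive integer")
  if (n < k) stop("need at least k observations (n = ", n, ", k = ", k, ")")
  if (!all(is.finite(x))) stop("observations must be finite")

  starts <- list(quantile_start(x, k))
  if (n_start > 1) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_start - 1), function(i) random_start(x, k))
    })
    starts <- c(starts, extra)
  }
  fits <- lapply(starts, function(s) {
    em_gaussian_1d(x, s, max_iter = max_iter, tol = tol, var_floor = var_floor)
  })
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- fits[[which.max(ll)]]
  # report components in increasing-mean order
  ord <- order(best$means)
  structure(
    list(k = k,
         weights = best$weights[ord],
         means = best$means[ord],
         variances = best$variances[ord],
         loglik = best$loglik,
         loglik_trace = best$loglik_trace,
         aic = 2 * (3 * k - 1) - 2 * best$loglik,
         converged = best$converged,
         responsibilities = best$responsibilities[, ord, drop = FALSE],
         n = n),
    class = "mixture_fit"
  )
}

quantile_start <- function(x, k) {
  list(weights = rep(1 / k, k),
       means = as.numeric(stats::quantile(x, (seq_len(k) - 0.5) / k)),
       variances = rep(max(stats::var(x), 1e-4), k))
}

random_start <- function(x, k) {
  list(weights = rep(1 / k, k),
       means = sample(x, k),
       variances = rep(max(stats::var(x), 1e-4), k))
}

em_gaussian_1d <- function(x, init, max_iter, tol, var_floor) {
  n <- length(x)
  k <- length(init$means)
  w <- init$weights; mu <- init$means; v <- pmax(init$variances, var_floor)
  trace <- numeric(0)
  converged <- FALSE
  collapsed <- FALSE
  resp <- matrix(1 / k, n, k)
  for (iter in seq_len(max_iter)) {
    # E step
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sqrt(v[j]))
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    if (iter > 1) {
      prev <- trace[iter - 1]
      if (abs(ll - prev) < tol * (abs(prev) + tol)) {
        converged <- TRUE
        break
      }
    }
    # M step
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- colSums(resp * (outer(x, mu, "-"))^2) / nk
    if (any(v < var_floor)) collapsed <- TRUE
    v <- pmax(v, var_floor)
  }
  list(weights = w, means = mu, variances = v,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged && !collapsed,
       responsibilities = resp)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, AIC = %.4f, %s\n",
              x$k, x$n, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                j, x$weights[j], x$means[j], sqrt(x$variances[j])))
  }
  invisible(x)
}

#' Select the number of mixture components by AIC
#'
#' Fits each candidate component count and returns the converged fit with
#' the lowest AIC; non-converged candidates are excluded from the
#' comparison, matching how a non-converging 3-component model is dropped.
#'
#' @param plvs Numeric observations.
#' @param k_candidates Candidate component counts (default 1:3); candidates
#'   exceeding the sample size are skipped.
#' @param ... Passed to [fit_gmm()].
#' @return The winning `mixture_fit`; the AICs of all converged candidates
#'   are attached as the `"aic_by_k"` attribute.
#' @export
select_k_by_aic <- function(plvs, k_candidates = 1:3, ...) {
  k_candidates <- k_candidates[k_candidates <= length(plvs)]
  if (length(k_candidates) == 0) stop("no feasible candidate k")
  fits <- lapply(k_candidates, function(k) fit_gmm(plvs, k, ...))
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) stop("no candidate mixture model converged")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- fits[[which(ok)[which.min(aics[ok])]]]
  attr(best, "aic_by_k") <- stats::setNames(aics, paste0("k", k_candidates))
  attr(best, "converged_by_k") <- stats::setNames(ok, paste0("k", k_candidates))
  best
}

#' Classify participants as high or low synchronizers
#'
#' Each observation is assigned to the mixture component with the larger
#' posterior responsibility; the component with the larger mean is labelled
#' `"high"`. Posterior ties are broken toward `"low"` (conservative).
#'
#' @param fit A two-component `mixture_fit`.
#' @param plvs The observations to label (default: those the fit saw, via
#'   responsibilities).
#' @return An object of class `classification`: `labels`, `n_high`,
#'   `n_low`, `boundary_plv` (PLV where the posteriors cross between the
#'   component means, `NA` if none), `posterior_high`.
#' @export
classify <- function(fit, plvs) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k != 2) stop("classification requires a 2-component fit")
  x <- as.numeric(plvs)
  hi <- which.max(fit$means)  # components are mean-ordered, but be explicit
  lo <- 3 - hi
  post <- posterior_2comp(x, fit)
  labels <- ifelse(post[, hi] > post[, lo], "high", "low")  # ties -> low
  boundary <- tryCatch(
    stats::uniroot(function(z) {
      p <- posterior_2comp(z, fit)
      p[, hi] - p[, lo]
    }, lower = fit$means[lo], upper = fit$means[hi], tol = 1e-9)$root,
    error = function(e) NA_real_
  )
  structure(
    list(labels = labels,
         n_high = sum(labels == "high"),
         n_low = sum(labels == "low"),
         boundary_plv = boundary,
         posterior_high = post[, hi]),
    class = "classification"
  )
}

posterior_2comp <- function(x, fit) {
  d <- vapply(1:2, function(j) {
    fit$weights[j] * stats::dnorm(x, fit$means[j], sqrt(fit$variances[j]))
  }, numeric(length(x)))
  d <- matrix(d, ncol = 2)
  s <- rowSums(d)
  s[s == 0] <- .Machine$double.xmin
  d / s
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %d high / %d low synchronizers (boundary PLV %.3f)\n",
              x$n_high, x$n_low, x$boundary_plv))
  invisible(x)
}
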