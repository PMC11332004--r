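#' One-sample Kolmogorov-Smirnov test against a reference distribution
#'
#' D is the supremum distance between the empirical CDF of `x` and the
#' reference CDF. The default reference is the standard normal applied to
#' the raw data without standardizing — the convention under which PLV data
#' concentrated in `[0, 1]` yield the large D values used as an effect size
#' for non-normality. Set `standardize = TRUE` for a location/scale-adjusted
#' (Lilliefors-style) variant; its p-value should then be obtained by Monte
#' Carlo rather than the asymptotic formula.
#'
#' @param x Numeric sample.
#' @param standardize Standardize `x` by its own mean/sd first?
#' @param n_sim,level,seed Monte-Carlo settings for the confidence interval
#'   (10,000 simulations, 95% by default); `n_sim = 0` skips the CI.
#' @param ci_type What the Monte-Carlo CI brackets: the estimated p-value
#'   (default) or the null distribution of D.
#' @return An object of class `ks_result`: `d_stat`, `p_value`, `n`,
#'   `ci_low`, `ci_high`, `reference`.
#' @export
ks_one_sample <- function(x, standardize = FALSE, n_sim = 10000,
                          level = 0.95, seed = NULL,
                          ci_type = c("p_value", "statistic")) {
  if (length(x) < 1) stop("empty sample")
  ci_type <- match.arg(ci_type)
  z <- if (standardize) (x - mean(x)) / stats::sd(x) else x
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  ci <- c(NA_real_, NA_real_)
  if (n_sim > 0) {
    n <- length(x)
    sim <- function() {
      suppressWarnings(stats::ks.test(stats::rnorm(n), "pnorm"))$statistic
    }
    ci <- mc_confidence_interval(observed = unname(kt$statistic),
                                 simulate_stat = sim, n_sim = n_sim,
                                 level = level, seed = seed, type = ci_type)
  }
  structure(
    list(d_stat = unname(kt$statistic), p_value = kt$p.value, n = length(x),
         ci_low = ci[1], ci_high = ci[2],
         reference = if (standardize) "standardized_normal" else "standard_normal"),
    class = "ks_result"
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the asymptotic
#' two-sided p-value is reported, with an optional Monte-Carlo confidence
#' interval under the pooled null.
#'
#' @param x,y Numeric samples.
#' @inheritParams ks_one_sample
#' @return A `ks_result` with `n = c(length(x), length(y))`.
#' @export
ks_two_sample <- function(x, y, n_sim = 10000, level = 0.95, seed = NULL,
                          ci_type = c("p_value", "statistic")) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample")
  ci_type <- match.arg(ci_type)
  kt <- suppressWarnings(stats::ks.test(x, y))
  ci <- c(NA_real_, NA_real_)
  if (n_sim > 0) {
    pool <- c(x, y)
    n1 <- length(x); n2 <- length(y)
    sim <- function() {
      idx <- sample.int(n1 + n2, n1)
      suppressWarnings(stats::ks.test(pool[idx], pool[-idx]))$statistic
    }
    ci <- mc_confidence_interval(observed = unname(kt$statistic),
                                 simulate_stat = sim, n_sim = n_sim,
                                 level = level, seed = seed, type = ci_type)
  }
  structure(
    list(d_stat = unname(kt$statistic), p_value = kt$p.value,
         n = c(length(x), length(y)),
         ci_low = ci[1], ci_high = ci[2], reference = "two_sample"),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D(%s) = %.3f, p = %.4g, CI [%.4g, %.4g] (%s)\n",
              paste(x$n, collapse = ", "), x$d_stat, x$p_value,
              x$ci_low, x$ci_high, x$reference))
  invisible(x)
}

#' Monte-Carlo confidence interval for a test quantity
#'
#' Simulates the statistic under the null `n_sim` times (seeded). With
#' `type = "statistic"` the percentile interval of the simulated null
#' distribution is returned: exactly `floor((1 - level)/2 * n_sim)`
#' simulated values fall below the lower bound. With `type = "p_value"`
#' (the default) the interval brackets the Monte-Carlo estimate of the
#' p-value `P(stat >= observed)` via the Clopper-Pearson binomial interval.
#'
#' @param observed Observed statistic (needed for `type = "p_value"`).
#' @param simulate_stat Zero-argument function returning one null draw.
#' @param n_sim Number of simulations (default 10,000; < 100 warns).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @param type `"p_value"` or `"statistic"`.
#' @return Numeric `c(low, high)`; for `"p_value"` the point estimate is
#'   attached as attribute `"estimate"`.
#' @export
mc_confidence_interval <- function(observed = NULL, simulate_stat,
                                   n_sim = 10000, level = 0.95, seed = NULL,
                                   type = c("p_value", "statistic")) {
  type <- match.arg(type)
  if (n_sim < 100) warning("n_sim < 100: Monte-Carlo interval will be crude")
  draws <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) as.numeric(simulate_stat()), numeric(1))
  })
  if (type == "statistic") {
    s <- sort(draws)
    m <- floor((1 - level) / 2 * n_sim)
    return(c(s[m + 1], s[n_sim - m]))
  }
  if (is.null(observed)) stop("observed statistic required for a p-value CI")
  hits <- sum(draws >= observed)
  ci <- stats::binom.test(hits, n_sim, conf.level = level)$conf.int
  out <- c(ci[1], ci[2])
  attr(out, "estimate") <- hits / n_sim
  out
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided test of a location difference between independent samples.
#' The p-value is exact (full null enumeration) when the combined sample
#' size is at most 16 and there are no ties; otherwise the normal
#' approximation with tie correction is used. The effect size is the
#' rank-biserial correlation `r = 1 - 2U/(n1 n2)`, where `U` counts pairs
#' in which the `x` observation exceeds the `y` observation.
#'
#' @param x,y Numeric samples (e.g. high vs low synchronizers' covariate).
#' @param exact_limit Combined sample size at or below which the exact
#'   p-value is used (default 16).
#' @return An object of class `rank_test_result`: `u_stat`, `p_value`,
#'   `rank_biserial_r`, `group_summaries`, `n`.
#' @export
mann_whitney <- function(x, y, exact_limit = 16) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  use_exact <- (n1 + n2) <= exact_limit && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  u <- unname(wt$statistic)  # number of (x > y) pairs, ties counted 1/2
  structure(
    list(u_stat = u, p_value = wt$p.value,
         rank_biserial_r = 1 - 2 * u / (n1 * n2),
         exact = use_exact,
         group_summaries = data.frame(
           group = c("x", "y"),
           n = c(n1, n2),
           median = c(stats::median(x), stats::median(y)),
           mean = c(mean(x), mean(y)),
           sd = c(stats::sd(x), stats::sd(y))
         ),
         n = c(n1, n2)),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank_test_result> U = %g, p = %.4g (%s), rank-biserial r = %.3f\n",
              x$u_stat, x$p_value, if (x$exact) "exact" else "approximate",
              x$rank_biserial_r))
  invisible(x)
}

#' Fisher's exact test with sample odds ratio and Woolf interval
#'
#' Two-sided exact test on a 2x2 contingency table (rows: exposure, e.g.
#' male/female; columns: outcome, e.g. high/low synchronizer). The p-value
#' sums hypergeometric probabilities of tables no more probable than the
#' observed one. The effect size is the sample cross-product odds ratio
#' `ad/bc` — with the conventional layout, the odds of a male participant
#' being a high synchronizer relative to a female participant — with a
#' Woolf (log-normal) confidence interval
#' `exp(log OR +/- z * sqrt(sum(1/counts)))`. The conditional-MLE estimate
#' is also reported for comparison. A zero cell makes the sample OR 0 or
#' infinite; it is reported as such with a warning (no continuity
#' correction).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param level Confidence level for the Woolf interval (default 0.95).
#' @return An object of class `contingency_result`: `table`, `odds_ratio`,
#'   `odds_ratio_cmle`, `or_ci`, `p_value`.
#' @export
fisher_exact <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (any(tab == 0)) {
    warning("zero cell: sample odds ratio is 0 or infinite; Woolf CI undefined")
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(sum(1 / tab))
    ci <- exp(log(or) + c(-z, z) * se)
  }
  structure(
    list(table = tab, odds_ratio = unname(or),
         odds_ratio_cmle = unname(ft$estimate),
         or_ci = ci, p_value = ft$p.value),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> OR = %.3f (Woolf CI [%.3f, %.3f]), p = %.4g\n",
              x$odds_ratio, x$or_ci[1], x$or_ci[2], x$p_value))
  invisible(x)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Two-sided rank-order correlation with average ranks for ties; the
#' confidence interval is `tanh(atanh(rho) +/- z / sqrt(n - 3))`.
#'
#' @param x,y Equal-length numeric samples, `n >= 3`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `correlation_result`: `rho`, `p_value`, `ci`,
#'   `n`.
#' @export
spearman_cor <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE)
  )
  rho <- unname(ct$estimate)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (abs(rho) < 1 && length(x) > 3) {
    tanh(atanh(rho) + c(-z, z) / sqrt(length(x) - 3))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(rho = rho, p_value = ct$p.value, ci = ci, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho(%d) = %.3f, p = %.4g, CI [%.3f, %.3f]\n",
              x$n, x$rho, x$p_value, x$ci[1], x$ci[2]))
  invisible(x)
}

#' JZS Bayes factor for a two-sample comparison
#'
#' Rouder-style Jeffreys-Zellner-Siow Bayes factor for the null hypothesis
#' of no standardized group difference: a Cauchy prior with scale
#' `prior_scale` on the effect size delta, integrated by adaptive
#' quadrature. The test statistic is the Welch (unequal-variance) t with
#' Welch degrees of freedom. `bf01 > 1` favors the null. The posterior mean
#' and central credible interval of delta are obtained from the same
#' quadrature.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param prior_scale Cauchy prior scale on delta (default `sqrt(2)/2`).
#' @param tol Quadrature relative tolerance (default 1e-5).
#' @param level Credible level (default 0.95).
#' @return An object of class `bayes_factor_result`: `bf01`, `bf10`,
#'   `posterior_mean`, `credible_interval`, `t`, `df`.
#' @export
bayes_factor_ttest <- function(x, y, prior_scale = sqrt(2) / 2, tol = 1e-5,
                               level = 0.95) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  n_eff <- n1 * n2 / (n1 + n2)

  # marginal likelihood of t under H1: noncentral t mixed over the Cauchy prior
  h1_density <- function(delta) {
    # dt(ncp) emits spurious precision warnings far in the tails
    suppressWarnings(stats::dt(t_stat, df = df, ncp = delta * sqrt(n_eff))) *
      stats::dcauchy(delta, 0, prior_scale)
  }
  m1 <- stats::integrate(h1_density, -Inf, Inf, rel.tol = tol,
                         subdivisions = 2000L, stop.on.error = FALSE)
  if (m1$message != "OK" || !is.finite(m1$value) || m1$value <= 0) {
    stop("quadrature for the marginal likelihood did not converge")
  }
  m0 <- stats::dt(t_stat, df = df)
  bf01 <- m0 / m1$value

  post_mean <- stats::integrate(function(d) d * h1_density(d), -Inf, Inf,
                                rel.tol = tol, subdivisions = 2000L,
                                stop.on.error = FALSE)$value / m1$value
  ci <- posterior_delta_interval(h1_density, m1$value, level)

  structure(
    list(bf01 = bf01, bf10 = 1 / bf01, posterior_mean = post_mean,
         credible_interval = ci, t = t_stat, df = df,
         prior_scale = prior_scale),
    class = "bayes_factor_result"
  )
}

# Central credible interval of delta by grid inversion of the posterior CDF.
posterior_delta_interval <- function(h1_density, norm, level) {
  grid <- seq(-6, 6, length.out = 4001)
  dens <- h1_density(grid) / norm
  cdf <- cumsum(dens) * (grid[2] - grid[1])
  cdf <- cdf / cdf[length(cdf)]
  a <- (1 - level) / 2
  c(grid[which.min(abs(cdf - a))], grid[which.min(abs(cdf - (1 - a)))])
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf(
    "<bayes_factor_result> BF01 = %.3f (t = %.3f, df = %.1f), posterior mean %.3f, CrI [%.3f, %.3f]\n",
    x$bf01, x$t, x$df, x$posterior_mean,
    x$credible_interval[1], x$credible_interval[2]))
  invisible(x)
}
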