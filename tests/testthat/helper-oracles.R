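# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each statistic from its definition and stay
# independent of the package code paths they verify.

# Windowed PLV by direct evaluation of the modulus-of-mean-phasor formula,
# enumerating window start indices explicitly.
plv_brute_force <- function(theta1, theta2, fs, window_s, overlap_s) {
  win <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  n <- length(theta1)
  plvs <- c()
  s <- 1
  while (s + win - 1 <= n) {
    acc <- 0 + 0i
    for (t in s:(s + win - 1)) {
      acc <- acc + exp(1i * (theta1[t] - theta2[t]))
    }
    plvs <- c(plvs, Mod(acc) / win)
    s <- s + hop
  }
  plvs
}

# One-sample KS statistic: sup over all jump points of the two one-sided
# deviations from the reference CDF.
ks1_brute_force <- function(x, cdf = pnorm) {
  x <- sort(x)
  n <- length(x)
  d <- 0
  for (i in seq_len(n)) {
    d <- max(d, abs(i / n - cdf(x[i])), abs((i - 1) / n - cdf(x[i])))
  }
  d
}

# Two-sample KS statistic: sup |F_x - F_y| over the pooled jump points.
ks2_brute_force <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (p in pts) {
    d <- max(d, abs(mean(x <= p) - mean(y <= p)))
  }
  d
}

# Fisher two-sided p by enumeration of all tables with the observed margins:
# sum of hypergeometric probabilities not exceeding the observed table's.
fisher_brute_force <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_brute_force <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Spearman rho as Pearson correlation of average ranks.
spearman_brute_force <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Small helpers shared across test files -------------------------------------

# A short stimulus envelope for fast end-to-end tests.
quick_stimulus <- function(rates = c(4.3, 4.4, 4.5, 4.6, 4.7),
                           plateau_s = 10, fs = 200) {
  generate_stimulus_envelope(stimulus_spec(rates, plateau_s, fs))
}

# Mean PLV of one simulated participant against a stimulus envelope.
simulated_plv <- function(stim, kappa = 16, mode = "coupled",
                          self_rate = 4.5, seed = 1) {
  sp <- participant_spec(coupling_kappa = kappa, mode = mode,
                         self_rate_hz = self_rate, seed = seed)
  participant_plv(stim, simulate_production(stim, sp))$plv_mean
}
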