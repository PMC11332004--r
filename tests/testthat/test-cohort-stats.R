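test_that("one-sample KS statistic matches hand-derived cases", {
  # single observation at 0: |F_n - Phi| jumps between 0 and 1 at Phi(0) = 0.5
  r <- ks_one_sample(0, n_sim = 0)
  expect_equal(r$d_stat, 0.5)
  expect_error(ks_one_sample(numeric(0)), "empty")
})

test_that("KS statistics equal O(n^2) brute force on random samples", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n, runif(1, -1, 1), runif(1, 0.5, 2))
    expect_equal(ks_one_sample(x, n_sim = 0)$d_stat, ks1_brute_force(x),
                 tolerance = 1e-12)
    m <- sample(3:40, 1)
    y <- rnorm(m, runif(1, -1, 1), runif(1, 0.5, 2))
    r2 <- ks_two_sample(x, y, n_sim = 0)
    expect_equal(r2$d_stat, ks2_brute_force(x, y), tolerance = 1e-12)
    expect_true(r2$d_stat >= 0 && r2$d_stat <= 1)
  }
})

test_that("two-sample KS behaves on degenerate configurations", {
  x <- c(0.2, 0.5, 0.9)
  expect_equal(ks_two_sample(x, x, n_sim = 0)$d_stat, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4), n_sim = 0)$d_stat, 1)
  expect_error(ks_two_sample(numeric(0), x), "empty")
})

test_that("large normal samples drive D toward zero with uniform p", {
  set.seed(5)
  ps <- replicate(100, ks_one_sample(rnorm(400), n_sim = 0)$p_value)
  ds <- replicate(100, ks_one_sample(rnorm(400), n_sim = 0)$d_stat)
  expect_lt(mean(ds), 0.06)
  # under the null the p-values are roughly uniform
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps > 0.5), 0.7)
})

test_that("Monte-Carlo intervals are definitional, seeded, and widen", {
  # percentile interval: exactly floor(0.025 n) draws below the lower bound
  sim <- function() rnorm(1)
  ci <- mc_confidence_interval(simulate_stat = sim, n_sim = 1000,
                               level = 0.95, seed = 9, type = "statistic")
  set.seed(9)
  vals <- rnorm(1000)
  expect_equal(sum(vals < ci[1]), floor(0.025 * 1000))
  expect_equal(sum(vals > ci[2]), floor(0.025 * 1000))

  # reproducible under the same seed
  ci2 <- mc_confidence_interval(simulate_stat = sim, n_sim = 1000,
                                level = 0.95, seed = 9, type = "statistic")
  expect_identical(ci, ci2)

  # degenerate statistic: zero-width interval
  cid <- mc_confidence_interval(simulate_stat = function() 1, n_sim = 500,
                                seed = 2, type = "statistic")
  expect_equal(cid[1], cid[2])

  # higher level widens the interval
  ci99 <- mc_confidence_interval(simulate_stat = sim, n_sim = 1000,
                                 level = 0.99, seed = 9, type = "statistic")
  expect_lte(ci99[1], ci[1])
  expect_gte(ci99[2], ci[2])

  # p-value interval brackets the estimate
  cip <- mc_confidence_interval(observed = 1.5, simulate_stat = sim,
                                n_sim = 2000, seed = 4, type = "p_value")
  est <- attr(cip, "estimate")
  expect_true(cip[1] <= est && est <= cip[2])
  expect_warning(mc_confidence_interval(observed = 0, simulate_stat = sim,
                                        n_sim = 50, seed = 1), "crude")
})

test_that("Mann-Whitney matches enumeration on the textbook case", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_stat, 0)
  expect_equal(r$p_value, 0.1)          # 2/20 arrangements as extreme
  expect_equal(r$rank_biserial_r, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("identical groups have zero rank-biserial correlation", {
  x <- c(3, 1, 4, 1, 5)
  r <- mann_whitney(x, x)
  expect_equal(r$rank_biserial_r, 0)
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  set.seed(23)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- round(rnorm(n1), 2)
      y <- round(rnorm(n2) + 0.5, 2)
      if (any(duplicated(c(x, y)))) next
      got <- mann_whitney(x, y)
      expect_true(got$exact)
      expect_equal(got$p_value, mw_brute_force(x, y), tolerance = 1e-9)
    }
  }
})

test_that("large-sample Mann-Whitney holds its type-I error", {
  set.seed(31)
  reps <- 2000
  rejections <- sum(replicate(reps, {
    mann_whitney(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gte(rejections / reps, 0.03)
  expect_lte(rejections / reps, 0.07)
})

test_that("Fisher test reproduces the sex-by-group contingency analysis", {
  # highs: 14 male / 11 female; lows: 5 male / 31 female
  tab <- matrix(c(14, 5, 11, 31), nrow = 2, byrow = TRUE,
                dimnames = list(c("male", "female"), c("high", "low")))
  r <- fisher_exact(tab)
  expect_equal(r$odds_ratio, 7.89, tolerance = 0.001)
  expect_equal(r$or_ci[1], 2.30, tolerance = 0.005)
  expect_equal(r$or_ci[2], 27.03, tolerance = 0.005)
  expect_lt(r$p_value, 0.001)
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(17)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(2:12, 1)), 2)
    got <- suppressWarnings(fisher_exact(tab))
    expect_equal(got$p_value, fisher_brute_force(tab), tolerance = 1e-9)
  }
})

test_that("Fisher handles flat and zero-cell tables", {
  flat <- fisher_exact(matrix(1, 2, 2))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  expect_warning(diag5 <- fisher_exact(matrix(c(5, 0, 0, 5), 2)), "zero cell")
  expect_equal(diag5$p_value, 2 / 252, tolerance = 1e-9)
  expect_error(fisher_exact(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Spearman correlation matches rank-Pearson with ties", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)  # forces ties
    y <- x + sample(1:5, n, replace = TRUE)
    expect_equal(spearman_cor(x, y)$rho, spearman_brute_force(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(1:5, 1:4), "equal length")
  expect_error(spearman_cor(1:2, 1:2), "3 pairs")
})

test_that("Spearman confidence interval brackets the estimate", {
  set.seed(3)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  r <- spearman_cor(x, y)
  expect_true(r$ci[1] < r$rho && r$rho < r$ci[2])
  expect_true(abs(r$rho) <= 1)
})

test_that("Bayes factor favors the null when groups coincide", {
  set.seed(19)
  bfs <- replicate(20, {
    bayes_factor_ttest(rnorm(60, 0.5, 0.15), rnorm(61, 0.5, 0.15))$bf01
  })
  expect_gt(mean(bfs > 1), 0.8)
})

test_that("Bayes factor detects a three-sigma separation", {
  set.seed(29)
  b <- bayes_factor_ttest(rnorm(50, 0, 1), rnorm(50, 3, 1))
  expect_lt(b$bf01, 0.1)
  expect_gt(b$bf10, 10)
})

test_that("Bayes factor is symmetric in its arguments", {
  set.seed(37)
  x <- rnorm(30, 0.4, 0.1)
  y <- rnorm(35, 0.5, 0.12)
  expect_equal(bayes_factor_ttest(x, y)$bf01, bayes_factor_ttest(y, x)$bf01,
               tolerance = 1e-6)
  expect_error(bayes_factor_ttest(1, rnorm(10)), "n >= 2")
})
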