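test_that("pearson_r matches hand computations and validates", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
})

test_that("effect-size algebra: d from t, t from d, and the CI", {
  expect_equal(round(d_from_t(15.7, 86), 2), 1.69)
  expect_equal(round(d_from_t(36.01, 86), 2), 3.88)
  expect_equal(d_from_t(0, 17), 0)
  for (d in c(-1, 0.3, 2)) expect_equal(d_from_t(t_from_d(d, 23), 23), d)
  # CI via the normal approximation with SE = sqrt(1/n + d^2/(2n))
  d <- d_from_t(15.7, 86)
  se <- sqrt(1 / 86 + d^2 / 172)
  set.seed(110)
  y <- scale(rnorm(86))[, 1] + d  # sample with exact mean d, sd 1
  out <- cohen_d_one_sample(y)
  expect_named(out, c("d", "ci_low", "ci_high", "n"))
  expect_equal(out$d, d, tolerance = 1e-10)
  expect_equal(out$ci_low, d - qnorm(0.975) * se, tolerance = 1e-10)
  expect_equal(out$ci_high, d + qnorm(0.975) * se, tolerance = 1e-10)
  expect_equal(round(c(out$ci_low, out$ci_high), 2), c(1.36, 2.02))
  # the noncentral-t interval is close to the approximation at this n
  nct <- cohen_d_one_sample(y, ci = "nct")
  expect_equal(nct$ci_low, out$ci_low, tolerance = 0.05)
  expect_equal(nct$ci_high, out$ci_high, tolerance = 0.05)
  expect_error(cohen_d_one_sample(rep(2, 5)), "zero SD")
})

test_that("JZS t-test BF: null behaviour, symmetry and monotonicity", {
  expect_lt(bf_ttest(0, 30)$bf10, 1)
  expect_equal(bf_ttest(-2.3, 40)$bf10, bf_ttest(2.3, 40)$bf10,
               tolerance = 1e-8)
  bfs <- vapply(c(0.5, 1, 2, 3, 5), function(t) bf_ttest(t, 40)$bf10,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  b <- bf_ttest(2, 30)
  expect_equal(b$bf01 * b$bf10, 1)
  expect_equal(b$df, 29)
  expect_error(bf_ttest(Inf, 30), "finite")
  expect_error(bf_ttest(1, 1), "at least 2")
})

test_that("two quadrature routes for the JZS BF agree", {
  # the g-mixture route (no noncentral t) vs the half-Cauchy route:
  # two.sided BF must equal the average of the two directional BFs
  for (t in c(0.7, 2, 4.5)) {
    two <- bf_ttest(t, 35)$bf10
    g <- bf_ttest(t, 35, alternative = "greater")$bf10
    l <- bf_ttest(t, 35, alternative = "less")$bf10
    expect_equal((g + l) / 2, two, tolerance = 1e-5)
  }
})

test_that("JZS BF matches a Monte-Carlo prior-average oracle", {
  # brute-force marginal likelihood: average the noncentral-t likelihood
  # over draws from the Cauchy prior
  set.seed(111)
  t_obs <- 2
  n <- 30
  deltas <- rcauchy(4e5, 0, sqrt(2) / 2)
  lik <- suppressWarnings(dt(t_obs, n - 1, ncp = deltas * sqrt(n)))
  mc <- mean(lik) / dt(t_obs, n - 1)
  mc_se <- sd(lik / dt(t_obs, n - 1)) / sqrt(4e5)
  expect_lt(abs(bf_ttest(t_obs, n)$bf10 - mc), 4 * mc_se)
})

test_that("correlation BF: symmetry, null accumulation and edge cases", {
  expect_equal(bf_correlation(-0.25, 50)$bf10, bf_correlation(0.25, 50)$bf10,
               tolerance = 1e-8)
  expect_lt(bf_correlation(0, 4)$bf10, 1)
  # evidence for the null grows with n at r = 0
  bf01s <- vapply(c(10, 30, 100, 300), function(n) bf_correlation(0, n)$bf01,
                  numeric(1))
  expect_true(all(diff(bf01s) > 0))
  expect_error(bf_correlation(1, 20), "degenerate")
  expect_error(bf_correlation(0.5, 3), "at least 4")
  expect_error(bf_correlation(0.5, 20, kappa = 0), "kappa")
})

test_that("correlation BF matches a Monte-Carlo prior-average oracle", {
  set.seed(112)
  r_obs <- 0.3
  n <- 40
  rhos <- runif(2e5, -1, 1)  # kappa = 1 prior is uniform
  ratio <- vapply(rhos, function(p) {
    exp(rtcit:::corr_log_reduced_lik(p, r_obs, n) -
          rtcit:::corr_log_reduced_lik(0, r_obs, n))
  }, numeric(1))
  mc <- mean(ratio)
  mc_se <- sd(ratio) / sqrt(2e5)
  expect_lt(abs(bf_correlation(r_obs, n)$bf10 - mc), 4 * mc_se)
})

test_that("quadratures are stable under a doubled resolution", {
  for (args in list(list(t = 2, n = 30), list(t = 15.7, n = 86))) {
    coarse <- bf_ttest(args$t, args$n, rel_tol = 1e-6)$bf10
    fine <- bf_ttest(args$t, args$n, rel_tol = 1e-12)$bf10
    expect_lt(abs(coarse - fine) / fine, 1e-6)
  }
  coarse <- bf_correlation(0.3, 40, rel_tol = 1e-6)$bf10
  fine <- bf_correlation(0.3, 40, rel_tol = 1e-12)$bf10
  expect_lt(abs(coarse - fine) / fine, 1e-6)
})

test_that("hypergeometric series agrees with known special cases", {
  # 2F1(1, 1; 2; z) = -log(1 - z) / z
  for (z in c(0.1, 0.5, 0.9)) {
    expect_equal(rtcit:::hyp2f1_series(1, 1, 2, z), -log(1 - z) / z,
                 tolerance = 1e-12)
  }
  # 2F1(a, b; b; z) = (1 - z)^(-a)
  expect_equal(rtcit:::hyp2f1_series(0.5, 3, 3, 0.4), (1 - 0.4)^-0.5,
               tolerance = 1e-12)
})

test_that("sequential BF trajectory is consistent and reproducible", {
  set.seed(113)
  x <- rnorm(60)
  y <- rnorm(60)
  traj <- sequential_bf(x, y, min_n = 5)
  expect_equal(traj$n, 5:60)
  full <- bf_correlation(pearson_r(x, y), 60)
  expect_equal(traj$bf10[nrow(traj)], full$bf10, tolerance = 1e-10)
  # deterministic given the data
  expect_identical(traj, sequential_bf(x, y, min_n = 5))
  expect_error(sequential_bf(x, y[-1]), "aligned")
})

test_that("under independence the null evidence accumulates on average", {
  set.seed(114)
  finals <- replicate(20, {
    x <- rnorm(86)
    y <- rnorm(86)
    c(early = bf_correlation(pearson_r(x[1:10], y[1:10]), 10)$bf01,
      final = bf_correlation(pearson_r(x, y), 86)$bf01)
  })
  expect_gt(median(finals["final", ]), median(finals["early", ]))
  expect_gt(mean(finals["final", ] > 1), 0.5)
})

test_that("bonferroni correction is alpha / m", {
  expect_equal(round(bonferroni_alpha(15), 3), 0.003)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(10, 0.01), 0.001)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("paired t matches hand computation", {
  expect_equal(paired_t(1:5, 1:5)$t, 0)
  res <- paired_t(c(3, 4, 5), c(1, 1, 1))
  expect_equal(res$t, 3 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_error(paired_t(1:3, 1:2), "equal length")
  # agrees with the reference implementation
  set.seed(115)
  a <- rnorm(20, 1)
  b <- rnorm(20)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(paired_t(a, b)$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(paired_t(a, b)$p, ref$p.value, tolerance = 1e-10)
})

test_that("correlation/BF matrix mirrors the pairwise computations", {
  set.seed(116)
  df <- data.frame(a = rnorm(40), b = rnorm(40))
  df$c <- df$a + rnorm(40)
  cm <- correlation_bf_matrix(df)
  expect_equal(cm$r["a", "c"], pearson_r(df$a, df$c))
  expect_equal(cm$bf10["a", "c"], bf_correlation(cm$r["a", "c"], 40)$bf10)
  expect_true(is.na(cm$bf10["c", "a"]))  # BFs above the diagonal only
  expect_equal(cm$display["c", "a"], sprintf("%.3f", cm$r["c", "a"]))
})
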