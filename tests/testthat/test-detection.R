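test_that("dCIT is the effect standardised by the irrelevant-RT SD", {
  df <- data.frame(mean_probe_rt_ms = c(500, 450),
                   mean_irrelevant_rt_ms = c(450, 450),
                   sd_irrelevant_rt_ms = c(50, 30))
  expect_equal(compute_dcit(df), c(1, 0))
  df$sd_irrelevant_rt_ms[1] <- 0
  expect_error(compute_dcit(df), "zero irrelevant-RT SD")
})

test_that("naive SD formula evaluates, bounds and degenerates correctly", {
  expect_equal(naive_sd(86, 0), sqrt((85 / 83) * (4 / 86)), tolerance = 1e-12)
  expect_equal(naive_sd(86, 0), 0.2183, tolerance = 1e-3)
  # delta inflates the SD via (1 + delta^2 / 8)
  expect_equal(naive_sd(86, 1) / naive_sd(86, 0), sqrt(1 + 1 / 8))
  expect_error(naive_sd(3), "N >= 4")
  # monotone decreasing in N, approaching 2 / sqrt(N)
  ns <- c(4:20, 50, 100, 1000, 10000)
  vals <- vapply(ns, naive_sd, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(naive_sd(10000, 0) / (2 / sqrt(10000)), 1, tolerance = 1e-3)
})

test_that("naive SD matches the Monte-Carlo SD of a null Cohen's d", {
  # oracle: two-group Cohen's d on N/2 + N/2 null normal samples
  set.seed(91)
  N <- 86
  d_vals <- replicate(4000, {
    a <- rnorm(N / 2)
    b <- rnorm(N / 2)
    sp <- sqrt((var(a) + var(b)) / 2)
    (mean(a) - mean(b)) / sp
  })
  mc_sd <- sd(d_vals)
  # MC SE of an SD estimate ~ sd / sqrt(2 (n - 1))
  expect_lt(abs(mc_sd - naive_sd(N, 0)), 4 * mc_sd / sqrt(2 * 3999))
})

test_that("simulated naive scores have the requested moments and seed contract", {
  set.seed(92)
  x <- simulate_naive(1e5, naive_sd(86, 0))
  expect_lt(abs(mean(x)), 3 * 0.2183 / sqrt(1e5))
  expect_equal(sd(x), 0.2183, tolerance = 0.01)
  set.seed(17)
  a <- simulate_naive(10, 1)
  set.seed(17)
  b <- simulate_naive(10, 1)
  expect_identical(a, b)
  expect_error(simulate_naive(0, 1))
  expect_error(simulate_naive(5, 0))
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(auc(c(0.5, 0.2), c(0.1, 0.3)), 0.75)
  expect_equal(auc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(auc(c(10, 11), c(1, 2)), 1)
  expect_error(auc(numeric(), 1), "non-empty")
  set.seed(93)
  for (i in 1:25) {
    k <- sample(seq(0, 2, by = 0.25), sample(1:20, 1), replace = TRUE)
    n <- sample(seq(0, 2, by = 0.25), sample(1:20, 1), replace = TRUE)
    expect_equal(auc(k, n), auc_brute_force(k, n))
  }
})

test_that("AUC invariances: complementarity and monotone transforms", {
  set.seed(94)
  k <- rnorm(40, 1)
  n <- rnorm(30)
  expect_equal(auc(k, n) + auc(n, k), 1)
  expect_equal(auc(exp(k), exp(n)), auc(k, n))
  expect_equal(auc(3 * k - 2, 3 * n - 2), auc(k, n))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(95)
  k <- rnorm(60, 0.8, 1)
  n <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 60), rep(0, 60)), predictor = c(k, n),
    direction = "<", quiet = TRUE)))
  expect_equal(auc(k, n), ref, tolerance = 1e-12)
})

test_that("bootstrap AUC behaves at the separability extremes", {
  set.seed(96)
  sep <- bootstrap_auc(rep(10, 20) + runif(20), N_formula = 86, n_boot = 200)
  expect_equal(sep$auc_mean, 1)
  expect_equal(sep$ci_low, 1)
  expect_equal(sep$ci_high, 1)
  null <- bootstrap_auc(rnorm(86, 0, naive_sd(86)), N_formula = 86,
                        n_boot = 400)
  expect_equal(null$auc_mean, 0.5, tolerance = 0.05)
  expect_true(null$ci_low <= null$auc_mean && null$auc_mean <= null$ci_high)
  expect_equal(null$naive_sd, naive_sd(86))
  expect_error(bootstrap_auc(1), "at least 2")
  expect_error(bootstrap_auc(rnorm(10), n_boot = 1), "n_boot")
})

test_that("bootstrap mean converges to the closed-form normal AUC", {
  # knowledgeable ~ N(mu, s): AUC = pnorm(mu / sqrt(s^2 + naive_sd^2))
  set.seed(97)
  mu <- 0.55
  s <- 0.32
  k <- rnorm(4000, mu, s)
  sdn <- naive_sd(86, 0)
  res <- bootstrap_auc(k, N_formula = 86, n_boot = 300, naive_n = 4000)
  expect_equal(res$auc_mean, pnorm(mu / sqrt(s^2 + sdn^2)), tolerance = 0.01)
})
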