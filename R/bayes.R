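#' Pearson correlation with validation
#'
#' @param x,y Equal-length numeric vectors (n >= 3), each with nonzero
#'   variance.
#' @return Sample Pearson correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' One-sample Cohen's d with confidence interval
#'
#' `d = mean(x) / sd(x)`. The 95% CI uses the normal approximation with
#' `SE = sqrt(1/n + d^2 / (2n))`; `ci = "nct"` instead inverts the noncentral
#' t distribution.
#'
#' @param x Numeric values (n >= 2, nonzero SD).
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"normal"` (default) or `"nct"`.
#' @return List with `d`, `ci_low`, `ci_high`, `n`.
#' @examples
#' cohen_d_one_sample(c(2, 3, 5, 6))
#' @export
cohen_d_one_sample <- function(x, conf_level = 0.95, ci = c("normal", "nct")) {
  ci <- match.arg(ci)
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero SD: effect size undefined", call. = FALSE)
  d <- mean(x) / s
  if (ci == "normal") {
    se <- sqrt(1 / n + d^2 / (2 * n))
    zc <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- d - zc * se
    hi <- d + zc * se
  } else {
    t_obs <- d * sqrt(n)
    a <- (1 - conf_level) / 2
    lims <- suppressWarnings(vapply(c(1 - a, a), function(p) {
      f <- function(ncp) stats::pt(t_obs, n - 1, ncp) - p
      stats::uniroot(f, c(-5, 5) * abs(t_obs) - c(50, -50),
                     extendInt = "downX")$root
    }, numeric(1)))
    lo <- lims[1] / sqrt(n)
    hi <- lims[2] / sqrt(n)
  }
  list(d = d, ci_low = lo, ci_high = hi, n = n)
}

#' @rdname cohen_d_one_sample
#' @param t One-sample t statistic.
#' @param n Sample size.
#' @export
d_from_t <- function(t, n) t / sqrt(n)

#' @rdname cohen_d_one_sample
#' @param d Standardised effect size.
#' @export
t_from_d <- function(d, n) d * sqrt(n)

#' Default (JZS) Bayes factor for a one-sample t test
#'
#' Compares the point null against a Cauchy prior on the standardised effect
#' (scale `sqrt(2)/2` by default, the convention of common Bayesian software).
#' The two-sided Bayes factor is computed by adaptive quadrature over the
#' implied inverse-gamma mixing distribution (numerically robust at extreme t
#' because it never evaluates a noncentral t density); the directional
#' variants integrate the noncentral-t marginal likelihood over the
#' corresponding half-Cauchy.
#'
#' @param t Observed t statistic.
#' @param n Sample size (>= 2).
#' @param cauchy_scale Cauchy prior scale on the effect size.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param rel_tol Quadrature relative tolerance.
#' @return An object of class `rtcit_bf` with `statistic_name = "t"`,
#'   `statistic_value`, `n`, `df`, `bf10`, `bf01` and a `prior` descriptor.
#' @examples
#' bf_ttest(2, 30)
#' bf_ttest(15.7, 86, alternative = "greater")  # ~9.5e23
#' @export
bf_ttest <- function(t, n, cauchy_scale = sqrt(2) / 2,
                     alternative = c("two.sided", "greater", "less"),
                     rel_tol = 1e-9) {
  alternative <- match.arg(alternative)
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  bf10 <- switch(alternative,
    two.sided = jzs_bf_g_quadrature(t, n, cauchy_scale, rel_tol),
    greater = jzs_bf_directional(t, n, cauchy_scale, 1, rel_tol),
    less = jzs_bf_directional(t, n, cauchy_scale, -1, rel_tol)
  )
  new_bf_result("t", t, n = n, df = n - 1, bf10 = bf10,
                prior = sprintf("Cauchy(0, %.4g), %s", cauchy_scale,
                                alternative))
}

# Two-sided JZS BF via the g-representation: a Cauchy(0, r) prior on the
# effect is an inverse-gamma(1/2, r^2/2) scale mixture of normals, giving a
# one-dimensional integral whose integrand is a likelihood RATIO (bounded,
# no extreme densities).
jzs_bf_g_quadrature <- function(t, n, r, rel_tol = 1e-9) {
  nu <- n - 1
  log_ratio <- function(g) {
    -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * (log1p(t^2 / ((1 + n * g) * nu)) - log1p(t^2 / nu))
  }
  integrand <- function(g) {
    exp(0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g) +
          log_ratio(g))
  }
  # substitute g = u / (1 - u) to integrate over (0, 1)
  f <- function(u) integrand(u / (1 - u)) / (1 - u)^2
  stats::integrate(Vectorize(f), 0, 1, rel.tol = rel_tol,
                   subdivisions = 500L)$value
}

# Directional JZS BF: marginal likelihood under a half-Cauchy (sign-restricted)
# prior, via the noncentral-t likelihood.
jzs_bf_directional <- function(t, n, r, sign = 1, rel_tol = 1e-9) {
  nu <- n - 1
  lik <- function(delta) {
    suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n)))
  }
  f <- function(delta) lik(sign * delta) * 2 * stats::dcauchy(delta, 0, r)
  num <- stats::integrate(Vectorize(f), 0, Inf, rel.tol = rel_tol,
                          subdivisions = 500L)$value
  num / stats::dt(t, nu)
}

#' Default Bayes factor for a Pearson correlation
#'
#' Compares the point null `rho = 0` against a stretched symmetric beta prior
#' on the correlation (width `kappa`; `kappa = 1` is uniform on (-1, 1), the
#' common software default), two-sided, using the exact reduced likelihood of
#' the sample correlation,
#' `f(rho) = (1 - rho^2)^((n-1)/2) (1 - rho r)^(3/2 - n)
#'   2F1(1/2, 1/2; n - 1/2; (rho r + 1)/2)`,
#' integrated by adaptive quadrature (the Gaussian hypergeometric factor is
#' summed to machine precision).
#'
#' @param r Sample correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param kappa Prior width (> 0).
#' @param rel_tol Quadrature relative tolerance.
#' @return An object of class `rtcit_bf` with `statistic_name = "r"`.
#' @examples
#' bf_correlation(0.038, 86)$bf01  # ~6.99
#' @export
bf_correlation <- function(r, n, kappa = 1, rel_tol = 1e-9) {
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (abs(r) >= 1) {
    stop("|r| = 1 is degenerate: evidence unbounded", call. = FALSE)
  }
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  a <- 1 / kappa
  prior <- function(rho) stats::dbeta((rho + 1) / 2, a, a) / 2
  loglik0 <- corr_log_reduced_lik(0, r, n)
  f <- function(rho) {
    vapply(rho, function(p) {
      exp(corr_log_reduced_lik(p, r, n) - loglik0) * prior(p)
    }, numeric(1))
  }
  bf10 <- stats::integrate(f, -1, 1, rel.tol = rel_tol,
                           subdivisions = 500L)$value
  new_bf_result("r", r, n = n, df = n - 2, bf10 = bf10,
                prior = sprintf("stretched beta, kappa = %.4g, two-sided",
                                kappa))
}

# rho-dependent part of the exact sampling density of a Pearson correlation
corr_log_reduced_lik <- function(rho, r, n) {
  ((n - 1) / 2) * log1p(-rho^2) + (1.5 - n) * log1p(-rho * r) +
    log(hyp2f1_series(0.5, 0.5, n - 0.5, (rho * r + 1) / 2))
}

# Gauss hypergeometric 2F1 by direct series; converges for |z| < 1 and, when
# c - a - b > 0, also at z = 1 (here c - a - b = n - 3/2).
hyp2f1_series <- function(a, b, c, z, max_terms = 10000L) {
  term <- 1
  s <- 1
  for (k in seq_len(max_terms) - 1L) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < abs(s) * 1e-16) return(s)
  }
  s
}

new_bf_result <- function(statistic_name, statistic_value, n, df, bf10,
                          prior) {
  if (!is.finite(bf10) || bf10 <= 0) {
    stop("Bayes factor computation failed (bf10 = ", bf10, ")", call. = FALSE)
  }
  structure(list(statistic_name = statistic_name,
                 statistic_value = statistic_value, n = n, df = df,
                 bf10 = bf10, bf01 = 1 / bf10, prior = prior),
            class = "rtcit_bf")
}

#' @export
print.rtcit_bf <- function(x, ...) {
  cat(sprintf("%s = %.4g (n = %d, df = %g): BF10 = %.4g, BF01 = %.4g\n",
              x$statistic_name, x$statistic_value, x$n, x$df, x$bf10,
              x$bf01))
  cat("  prior:", x$prior, "\n")
  invisible(x)
}

#' Sequential Bayes-factor trajectory for a correlation
#'
#' Recomputes the default correlation Bayes factor on the first `n` pairs for
#' `n = min_n, ..., length(x)`, tracing how the evidence accumulates as
#' participants are added in collection order.
#'
#' @param x,y Aligned numeric vectors in collection order.
#' @param min_n First sample size evaluated (default 5).
#' @param kappa Prior width for [bf_correlation()].
#' @return Tibble with columns `n`, `r`, `bf10`, `bf01`; the last row equals
#'   [bf_correlation()] on the full data.
#' @export
sequential_bf <- function(x, y, min_n = 5, kappa = 1) {
  if (length(x) != length(y) || length(x) < min_n) {
    stop("x and y must be aligned with length >= min_n", call. = FALSE)
  }
  ns <- seq.int(min_n, length(x))
  rows <- lapply(ns, function(n) {
    r <- pearson_r(x[seq_len(n)], y[seq_len(n)])
    b <- bf_correlation(r, n, kappa)
    tibble::tibble(n = n, r = r, bf10 = b$bf10, bf01 = b$bf01)
  })
  dplyr::bind_rows(rows)
}

#' Bonferroni-corrected alpha threshold
#'
#' @param m Number of comparisons (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(15)  # 0.00333...
#' @export
bonferroni_alpha <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Paired t test statistic
#'
#' Standard paired t on the differences `a - b`, with `df = n - 1` and a
#' two-sided p value.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @examples
#' paired_t(c(3, 4, 5), c(1, 1, 1))  # t = 5.196, df = 2
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must have equal length >= 2", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0 && mean(d) == 0) {
    return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, sd_diff = 0, n = n))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * stats::pt(-abs(t_stat), n - 1),
       mean_diff = mean(d), sd_diff = s, n = n)
}

#' Correlation / Bayes-factor matrix report
#'
#' Pairwise Pearson correlations and default correlation Bayes factors for a
#' set of measures, presented in the conventional compact layout: sample
#' correlations below the diagonal, Bayes factors above it (reported as BF10
#' when the data favour the alternative, otherwise as BF01, with a label
#' matrix saying which).
#'
#' @param data Data frame of numeric measures (columns are variables).
#' @param kappa Prior width for [bf_correlation()].
#' @return List with matrices `r`, `bf10`, `p` and a character `display`
#'   matrix (r below the diagonal, labelled BF above).
#' @export
correlation_bf_matrix <- function(data, kappa = 1) {
  m <- as.matrix(data)
  k <- ncol(m)
  n <- nrow(m)
  vars <- colnames(m)
  r_mat <- bf_mat <- p_mat <- matrix(NA_real_, k, k,
                                     dimnames = list(vars, vars))
  disp <- matrix("-", k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      r <- pearson_r(m[, i], m[, j])
      r_mat[i, j] <- r
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      p_mat[i, j] <- 2 * stats::pt(-abs(t_stat), n - 2)
      if (i < j) bf_mat[i, j] <- bf_correlation(r, n, kappa)$bf10
      disp[i, j] <- if (i > j) {
        sprintf("%.3f", r)
      } else {
        b <- bf_mat[i, j]
        if (b >= 1) sprintf("%.3g (BF10)", b) else sprintf("%.3g (BF01)", 1 / b)
      }
    }
  }
  list(r = r_mat, bf10 = bf_mat, p = p_mat, display = disp, n = n)
}
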