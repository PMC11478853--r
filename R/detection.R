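#' Standardised per-participant detection score (dCIT)
#'
#' The RT-CIT effect (mean probe RT minus mean irrelevant RT) divided by the
#' SD of that participant's retained irrelevant-trial RTs.
#'
#' @param summary A [summarize_participants()] tibble (or any data frame with
#'   `mean_probe_rt_ms`, `mean_irrelevant_rt_ms`, `sd_irrelevant_rt_ms`).
#' @return Numeric vector of dCIT scores.
#' @examples
#' compute_dcit(data.frame(mean_probe_rt_ms = 500,
#'   mean_irrelevant_rt_ms = 450, sd_irrelevant_rt_ms = 50))  # 1
#' @export
compute_dcit <- function(summary) {
  sd_i <- summary$sd_irrelevant_rt_ms
  bad <- !is.na(sd_i) & sd_i <= 0
  if (any(bad)) {
    stop("zero irrelevant-RT SD: dCIT undefined for participant(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  (summary$mean_probe_rt_ms - summary$mean_irrelevant_rt_ms) / sd_i
}

#' Sampling SD of a standardised mean difference
#'
#' The SD assigned to the simulated naive group's dCIT scores:
#' `sqrt(((N - 1) / (N - 3)) * (4 / N) * (1 + delta^2 / 8))`, the sampling
#' variance of Cohen's d for total sample size `N` and true population effect
#' `delta`. With `delta = 0` (naive participants cannot distinguish probes
#' from irrelevants) this reduces to `sqrt(((N - 1) / (N - 3)) * 4 / N)`,
#' approaching `2 / sqrt(N)` for large `N`.
#'
#' @param N Total sample size entering the variance formula (>= 4).
#' @param delta True population effect size (default 0).
#' @return Positive scalar SD.
#' @examples
#' naive_sd(86)  # ~0.2183
#' @export
naive_sd <- function(N, delta = 0) {
  if (N <= 3) stop("the variance formula requires N >= 4", call. = FALSE)
  sqrt(((N - 1) / (N - 3)) * (4 / N) * (1 + delta^2 / 8))
}

#' Draw a simulated naive group
#'
#' Unknowledgeable participants carry no systematic probe-irrelevant
#' difference, so their dCIT scores are modelled as i.i.d. Normal(0, sd).
#'
#' @param n Group size.
#' @param sd Positive SD, typically from [naive_sd()].
#' @return Numeric vector of n scores.
#' @export
simulate_naive <- function(n, sd) {
  stopifnot(n >= 1, sd > 0)
  stats::rnorm(n, 0, sd)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen knowledgeable score exceeds a randomly
#' chosen naive score, ties counted half: the area under the ROC curve of the
#' two-group classification.
#'
#' @param knowledgeable,naive Non-empty numeric score vectors.
#' @return AUC in [0, 1].
#' @examples
#' auc(c(0.5, 0.2), c(0.1, 0.3))  # 0.75
#' @export
auc <- function(knowledgeable, naive) {
  nk <- length(knowledgeable)
  nn <- length(naive)
  if (nk == 0 || nn == 0) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  r <- rank(c(knowledgeable, naive))  # midranks give ties half credit
  u <- sum(r[seq_len(nk)]) - nk * (nk + 1) / 2
  u / (nk * nn)
}

#' Bootstrap detection efficiency against a simulated naive group
#'
#' Repeats `n_boot` times: draw a fresh simulated naive sample (size
#' `naive_n`, SD from [naive_sd()]) and compute the rank-based AUC of the
#' observed knowledgeable dCIT scores against it. The knowledgeable scores
#' are held fixed by default; `resample_knowledgeable = TRUE` additionally
#' resamples them with replacement each repetition. The estimate is the mean
#' of the bootstrapped AUCs with a percentile 95% interval.
#'
#' @param dcits Observed knowledgeable dCIT scores (>= 2).
#' @param N_formula Sample size entering the naive-SD formula; defaults to
#'   the number of knowledgeable scores.
#' @param n_boot Bootstrap repetitions (default 1000).
#' @param naive_n Simulated naive group size; defaults to the knowledgeable
#'   group size.
#' @param delta True effect passed to [naive_sd()] (default 0).
#' @param resample_knowledgeable Also resample the knowledgeable scores?
#' @return An object of class `rtcit_detection`: list with `auc_mean`,
#'   `ci_low`, `ci_high`, `n_boot`, `naive_sd`, `n_knowledgeable`, and the
#'   per-repetition vector `auc_reps`.
#' @examples
#' set.seed(3)
#' bootstrap_auc(rnorm(86, 0.55, 0.32), n_boot = 200)
#' @export
bootstrap_auc <- function(dcits, N_formula = length(dcits), n_boot = 1000,
                          naive_n = length(dcits), delta = 0,
                          resample_knowledgeable = FALSE) {
  dcits <- dcits[!is.na(dcits)]
  if (length(dcits) < 2) {
    stop("need at least 2 knowledgeable scores", call. = FALSE)
  }
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  sd_naive <- naive_sd(N_formula, delta)
  reps <- vapply(seq_len(n_boot), function(i) {
    k <- if (resample_knowledgeable) {
      sample(dcits, length(dcits), replace = TRUE)
    } else {
      dcits
    }
    auc(k, simulate_naive(naive_n, sd_naive))
  }, numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  structure(list(auc_mean = mean(reps), ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, naive_sd = sd_naive,
                 n_knowledgeable = length(dcits), auc_reps = reps),
            class = "rtcit_detection")
}

#' @export
print.rtcit_detection <- function(x, ...) {
  cat(sprintf(paste0("Detection efficiency (simulated-naive bootstrap, %d",
                     " reps)\n  mean AUC = %.3f, 95%% CI [%.3f, %.3f]\n",
                     "  knowledgeable n = %d, naive SD = %.4f\n"),
              x$n_boot, x$auc_mean, x$ci_low, x$ci_high,
              x$n_knowledgeable, x$naive_sd))
  invisible(x)
}
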