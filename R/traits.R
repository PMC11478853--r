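#' Trait-model configuration for the cohort simulator
#'
#' Describes the population the simulator draws participants from: four
#' correlated standard-normal latent traits (primary psychopathy, secondary
#' psychopathy, impulsivity, response-inhibition capacity), the
#' between-subject distribution of the RT-CIT probe slowing, the baseline
#' irrelevant-item RT distribution, and the reliability targets used when the
#' latent traits are turned into Likert item responses.
#'
#' The latent correlations are, by default, disattenuated versions of the
#' target correlations among the SCORED scales: a scored-scale correlation of
#' `rho` between instruments with reliabilities `a1` and `a2` requires a
#' latent correlation of `rho / sqrt(a1 * a2)`, because item noise attenuates
#' each scale by `sqrt(alpha)`. With the default targets (secondary-BIS
#' 0.516, primary-secondary 0.300, primary-BIS 0.185; alphas 0.80 / 0.63 /
#' 0.84) the latent matrix entries are 0.709, 0.423 and 0.226. The inhibition
#' trait is uncorrelated with the others by default, encoding the observed
#' absence of a reliable association between no-go failures and the
#' questionnaire traits.
#'
#' Under the default configuration the probe slowing (`probe_shift`) is drawn
#' independently of every latent trait, so the simulated population satisfies
#' the null hypothesis of no association between the RT-CIT effect and
#' secondary psychopathy.
#'
#' @param target_scale_correlations Named numeric: desired Pearson
#'   correlations among scored scales (`primary_secondary`, `primary_bis`,
#'   `secondary_bis`).
#' @param reliabilities Named numeric in (0, 1]: Cronbach's alpha targets for
#'   `lsrp_primary`, `lsrp_secondary`, `bis`.
#' @param latent_correlation_matrix Optional 4x4 correlation matrix over
#'   (primary, secondary, impulsivity, inhibition); when `NULL` it is built
#'   from the disattenuated scale targets.
#' @param probe_shift_mean_ms,probe_shift_sd_ms Between-subject mean and SD of
#'   the additive probe slowing (ms).
#' @param target_shift_mean_ms,target_shift_sd_ms Between-subject distribution
#'   of the additive target slowing (ms).
#' @param base_rt_mean_ms,base_rt_between_sd_ms Between-subject mean and SD of
#'   the participant-level mean irrelevant RT (ms).
#' @param within_sd_irrelevant_ms Within-subject SD of irrelevant-trial RTs
#'   (ms); split between the Gaussian and exponential ex-Gaussian components.
#' @param tau_ms Exponential (tail) component of the ex-Gaussian; defaults to
#'   `within_sd_irrelevant_ms / sqrt(2)` (an even variance split).
#' @param commission_rate_mean Population mean probability of pressing on a
#'   no-go trial.
#' @param commission_logit_slope Slope linking (negated) inhibition capacity
#'   to the logit of the commission probability.
#' @param error_prob_go Probability of a wrong-button press on a go trial.
#' @param rating_means,rating_sds Named numeric (probe, irrelevant,
#'   motivation, impulsivity): post-test rating distributions before rounding
#'   and clipping.
#'
#' @return An object of class `rtcit_trait_config`.
#' @export
trait_model_config <- function(
    target_scale_correlations = c(primary_secondary = 0.300,
                                  primary_bis = 0.185,
                                  secondary_bis = 0.516),
    reliabilities = c(lsrp_primary = 0.80, lsrp_secondary = 0.63, bis = 0.84),
    latent_correlation_matrix = NULL,
    probe_shift_mean_ms = 54.91, probe_shift_sd_ms = 32.43,
    target_shift_mean_ms = 55, target_shift_sd_ms = 25,
    base_rt_mean_ms = 477.47, base_rt_between_sd_ms = 33.28,
    within_sd_irrelevant_ms = 100,
    tau_ms = within_sd_irrelevant_ms / sqrt(2),
    commission_rate_mean = 14.99 / 48,
    commission_logit_slope = 0.7,
    error_prob_go = 0.04,
    rating_means = c(probe = 8.58, irrelevant = 1.94,
                     motivation = 7.71, impulsivity = 6.22),
    rating_sds = c(probe = 1.21, irrelevant = 1.10,
                   motivation = 2.2, impulsivity = 2.16)) {
  if (any(reliabilities <= 0) || any(reliabilities > 1)) {
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(latent_correlation_matrix)) {
    latent_correlation_matrix <- disattenuated_latent_matrix(
      target_scale_correlations, reliabilities)
  }
  check_correlation_matrix(latent_correlation_matrix)
  if (probe_shift_sd_ms < 0 || within_sd_irrelevant_ms <= 0 ||
      tau_ms < 0 || tau_ms > within_sd_irrelevant_ms) {
    stop("RT dispersion parameters out of range", call. = FALSE)
  }
  if (commission_rate_mean < 0 || commission_rate_mean > 1 ||
      error_prob_go < 0 || error_prob_go > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  cfg <- list(
    target_scale_correlations = target_scale_correlations,
    reliabilities = reliabilities,
    latent_correlation_matrix = latent_correlation_matrix,
    probe_shift_mean_ms = probe_shift_mean_ms,
    probe_shift_sd_ms = probe_shift_sd_ms,
    target_shift_mean_ms = target_shift_mean_ms,
    target_shift_sd_ms = target_shift_sd_ms,
    base_rt_mean_ms = base_rt_mean_ms,
    base_rt_between_sd_ms = base_rt_between_sd_ms,
    within_sd_irrelevant_ms = within_sd_irrelevant_ms,
    tau_ms = tau_ms,
    commission_rate_mean = commission_rate_mean,
    commission_logit_slope = commission_logit_slope,
    error_prob_go = error_prob_go,
    rating_means = rating_means,
    rating_sds = rating_sds
  )
  class(cfg) <- "rtcit_trait_config"
  cfg
}

latent_trait_names <- c("z_primary", "z_secondary", "z_impulsivity",
                        "z_inhibition")

disattenuated_latent_matrix <- function(scale_cor, rel) {
  dis <- function(r, a1, a2) r / sqrt(a1 * a2)
  m <- diag(4)
  dimnames(m) <- list(latent_trait_names, latent_trait_names)
  m["z_primary", "z_secondary"] <- m["z_secondary", "z_primary"] <-
    dis(scale_cor[["primary_secondary"]], rel[["lsrp_primary"]],
        rel[["lsrp_secondary"]])
  m["z_primary", "z_impulsivity"] <- m["z_impulsivity", "z_primary"] <-
    dis(scale_cor[["primary_bis"]], rel[["lsrp_primary"]], rel[["bis"]])
  m["z_secondary", "z_impulsivity"] <- m["z_impulsivity", "z_secondary"] <-
    dis(scale_cor[["secondary_bis"]], rel[["lsrp_secondary"]], rel[["bis"]])
  m
}

check_correlation_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-8)) ||
      any(abs(diag(m) - 1) > 1e-8)) {
    stop("latent_correlation_matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("latent_correlation_matrix is not positive semi-definite",
         call. = FALSE)
  }
  invisible(m)
}

#' Draw participant-level latent traits and RT-model parameters
#'
#' Latent traits are multivariate standard normal with the configured
#' correlation matrix. The probe slowing is Normal(probe_shift_mean_ms,
#' probe_shift_sd_ms), independent of all latent traits under the default
#' configuration. Baseline irrelevant-RT parameters are chosen so that the
#' participant-level mean irrelevant RT (`mu + tau`) has the configured
#' between-subject mean and SD. The no-go commission probability follows a
#' logit-normal link on (negated) inhibition capacity, centred on the
#' configured population commission rate.
#'
#' @param n Number of participants.
#' @param config An [trait_model_config()] object.
#' @return A tibble with one row per participant: `participant_id`, the four
#'   latent traits, ex-Gaussian parameters `base_mu_ms`, `base_sigma_ms`,
#'   `base_tau_ms`, the additive `probe_shift_ms` and `target_shift_ms`, and
#'   the error probabilities `commission_prob` and `error_prob_go`.
#' @examples
#' set.seed(1)
#' tr <- sample_traits(5, trait_model_config())
#' @export
sample_traits <- function(n, config = trait_model_config()) {
  stopifnot(n >= 1)
  z <- MASS::mvrnorm(n, mu = rep(0, 4),
                     Sigma = config$latent_correlation_matrix)
  z <- matrix(z, nrow = n)
  colnames(z) <- latent_trait_names

  tau <- config$tau_ms
  sigma <- sqrt(config$within_sd_irrelevant_ms^2 - tau^2)
  base_mean <- stats::rnorm(n, config$base_rt_mean_ms,
                            config$base_rt_between_sd_ms)
  logit0 <- stats::qlogis(config$commission_rate_mean)

  tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    z_primary = z[, "z_primary"],
    z_secondary = z[, "z_secondary"],
    z_impulsivity = z[, "z_impulsivity"],
    z_inhibition = z[, "z_inhibition"],
    base_mu_ms = base_mean - tau,
    base_sigma_ms = sigma,
    base_tau_ms = tau,
    probe_shift_ms = stats::rnorm(n, config$probe_shift_mean_ms,
                                  config$probe_shift_sd_ms),
    target_shift_ms = stats::rnorm(n, config$target_shift_mean_ms,
                                   config$target_shift_sd_ms),
    commission_prob = stats::plogis(
      logit0 - config$commission_logit_slope * z[, "z_inhibition"]),
    error_prob_go = config$error_prob_go
  )
}
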