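#' Ex-Gaussian random deviates
#'
#' Sum of a Gaussian and an independent exponential component, the standard
#' convolution model for simple reaction times. Mean is `mu + tau`, variance
#' `sigma^2 + tau^2`. `tau = 0` degenerates to the Gaussian.
#'
#' @param n Number of draws.
#' @param mu,sigma Gaussian component mean and SD (`sigma > 0`).
#' @param tau Exponential component mean (`tau >= 0`).
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  if (any(sigma <= 0) || any(tau < 0)) {
    stop("sigma must be > 0 and tau >= 0", call. = FALSE)
  }
  x <- stats::rnorm(n, mu, sigma)
  pos <- tau > 0
  if (any(pos)) {
    e <- stats::rexp(n, 1)
    x <- x + e * tau  # tau recycled over n where vectorised
  }
  x
}

#' Simulate responses and latencies for a trial schedule
#'
#' Fills in `rt_ms`, `response` and `correct` for every trial stub produced by
#' [generate_schedule()]. Go-trial latencies are ex-Gaussian with the
#' participant's baseline parameters plus an additive shift on probes
#' (`probe_shift_ms`) and targets (`target_shift_ms`); a latency beyond the
#' stimulus window is recorded as an omission (no response, no RT). Wrong-button
#' presses occur with probability `error_prob_go`; no-go commissions occur
#' with probability `commission_prob` and, when they occur, carry a latency
#' drawn from the go distribution.
#'
#' @param schedule Trial stubs from [generate_schedule()] (one or many
#'   participants; matched to `traits` by `participant_id`).
#' @param traits Participant parameter table from [sample_traits()].
#' @param design The [design_spec()] used to build the schedule.
#' @return The schedule tibble with `rt_ms` (NA when no press), `response`
#'   (`"familiar"`, `"unfamiliar"` or `"none"`) and `correct` columns added.
#' @export
generate_rts <- function(schedule, traits, design = design_spec()) {
  validate_design(design)
  missing_ids <- setdiff(unique(schedule$participant_id),
                         traits$participant_id)
  if (length(missing_ids) > 0) {
    stop("traits missing for participants: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(schedule$participant_id, traits$participant_id)
  mu <- traits$base_mu_ms[idx]
  sigma <- traits$base_sigma_ms[idx]
  tau <- traits$base_tau_ms[idx]
  shift <- ifelse(schedule$stim_type == "probe", traits$probe_shift_ms[idx],
           ifelse(schedule$stim_type == "target", traits$target_shift_ms[idx],
                  0))
  n <- nrow(schedule)
  rt <- rexgauss(n, mu + shift, sigma, tau)
  neg <- which(rt <= 0)
  if (length(neg) > 0) {  # negligible mass; redraw then clamp
    rt[neg] <- rexgauss(length(neg), mu[neg] + shift[neg], sigma[neg],
                        tau[neg])
    rt <- pmax(rt, 1)
  }

  is_go <- schedule$stim_type != "nogo"
  pressed <- logical(n)
  pressed[is_go] <- rt[is_go] <= design$stim_duration_ms
  commit <- stats::runif(n) < traits$commission_prob[idx]
  pressed[!is_go] <- commit[!is_go] & rt[!is_go] <= design$stim_duration_ms

  correct_button <- ifelse(schedule$stim_type == "target", "familiar",
                           "unfamiliar")
  wrong <- stats::runif(n) < traits$error_prob_go[idx]
  response <- rep("none", n)
  go_press <- is_go & pressed
  response[go_press] <- ifelse(wrong[go_press],
                               flip_button(correct_button[go_press]),
                               correct_button[go_press])
  # commissions are failures to withhold the prepotent go response
  response[!is_go & pressed] <- "unfamiliar"

  out <- schedule
  out$rt_ms <- ifelse(pressed, round(rt, 1), NA_real_)
  out$response <- response
  out$correct <- trial_correct(out$stim_type, out$response)
  out
}

flip_button <- function(button) {
  ifelse(button == "familiar", "unfamiliar", "familiar")
}

# task rules: probes/irrelevants demand "unfamiliar", targets "familiar",
# no-go items demand withholding
trial_correct <- function(stim_type, response) {
  (stim_type %in% c("probe", "irrelevant") & response == "unfamiliar") |
    (stim_type == "target" & response == "familiar") |
    (stim_type == "nogo" & response == "none")
}
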