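#' Trial-level exclusion rules
#'
#' Applies the preregistered-style single-trial filters to go trials: a press
#' faster than `design$min_valid_rt_ms` (reason `rt_below_min`), a press
#' slower than `design$deadline_ms` (`rt_above_max`), or a wrong-button press
#' (`wrong_button`) excludes the trial from RT summaries. Omissions (go trials
#' with no press) are retained but carry no RT and enter no RT summary; no-go
#' trials pass through untouched, as they are scored separately for
#' commission errors. When several rules apply, the reason reported follows
#' the fixed order above.
#'
#' @param trials Trial tibble (one or many participants).
#' @param design The [design_spec()] defining the RT window.
#' @return A list with `retained` (trial tibble) and `exclusions` (tibble
#'   `participant_id`, `trial_index`, `reason`), partitioning the input:
#'   every row appears in exactly one of the two.
#' @examples
#' d <- design_spec()
#' tr <- tibble::tibble(participant_id = "p1", block = 1L, trial_index = 1:2,
#'   item_id = c("irrelevant_1", "probe_1"),
#'   stim_type = c("irrelevant", "probe"), isi_ms = 500,
#'   rt_ms = c(100, 400), response = "unfamiliar", correct = TRUE)
#' filter_trials(tr, d)$exclusions
#' @export
filter_trials <- function(trials, design = design_spec()) {
  is_go <- trials$stim_type != "nogo"
  pressed <- trials$response != "none"
  reason <- rep(NA_character_, nrow(trials))
  reason[is_go & pressed & !is.na(trials$rt_ms) &
           trials$rt_ms < design$min_valid_rt_ms] <- "rt_below_min"
  sel <- is.na(reason) & is_go & pressed & !is.na(trials$rt_ms) &
    trials$rt_ms > design$deadline_ms
  reason[sel] <- "rt_above_max"
  sel <- is.na(reason) & is_go & pressed & !trials$correct
  reason[sel] <- "wrong_button"

  excluded <- !is.na(reason)
  list(
    retained = trials[!excluded, , drop = FALSE],
    exclusions = tibble::tibble(
      participant_id = trials$participant_id[excluded],
      trial_index = trials$trial_index[excluded],
      reason = reason[excluded]
    )
  )
}

#' Participant-level inclusion decisions
#'
#' A participant is excluded when the session is incomplete (fewer trials than
#' the design prescribes) or when the error rate on go trials of ANY single
#' stimulus type (probe, irrelevant, target) reaches 50%. An error is a
#' wrong-button press or, when `count_omissions` (the default), an omission —
#' both invalidate a go trial. Reasons are evaluated in a fixed order
#' (incomplete session first, then probe, irrelevant, target error rates), so
#' each excluded participant carries exactly one primary reason.
#'
#' @param trials Trial tibble covering one or more participants.
#' @param design The [design_spec()].
#' @param count_omissions Should omitted go responses count as errors for the
#'   50% rule?
#' @return Tibble: `participant_id`, `n_trials`, `error_rate_probe`,
#'   `error_rate_irrelevant`, `error_rate_target`, `included`,
#'   `exclusion_reason` (NA when included).
#' @export
participant_qc <- function(trials, design = design_spec(),
                           count_omissions = TRUE) {
  full_n <- n_trials_total(design)
  err <- if (count_omissions) {
    !trials$correct  # wrong button or omission
  } else {
    trials$response != "none" & !trials$correct
  }
  trials$.err <- err
  by_p <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    n_trials = dplyr::n(),
    error_rate_probe = mean(.data$.err[.data$stim_type == "probe"]),
    error_rate_irrelevant = mean(.data$.err[.data$stim_type == "irrelevant"]),
    error_rate_target = mean(.data$.err[.data$stim_type == "target"]),
    .groups = "drop"
  )
  reason <- rep(NA_character_, nrow(by_p))
  reason[by_p$n_trials < full_n] <- "incomplete_session"
  for (st in c("probe", "irrelevant", "target")) {
    rate <- by_p[[paste0("error_rate_", st)]]
    sel <- is.na(reason) & !is.na(rate) & rate >= 0.5
    reason[sel] <- paste0("ge50pct_", st, "_errors")
  }
  by_p$included <- is.na(reason)
  by_p$exclusion_reason <- reason
  by_p
}

#' Per-participant RT-CIT summaries
#'
#' Runs the participant-level inclusion rules, the trial-level filters, and
#' computes for every participant the quantities the analysis consumes: mean
#' probe and irrelevant RT over RETAINED correct go presses, the sample SD of
#' retained irrelevant RTs, the RT-CIT effect (mean probe minus mean
#' irrelevant RT), its standardised form dCIT, per-type error rates, and no-go
#' commission counts over ALL no-go trials (commissions are never filtered;
#' the commission rate denominator is the designed number of no-go trials).
#'
#' @param trials Trial tibble covering one or more participants.
#' @param design The [design_spec()].
#' @param count_omissions Passed to [participant_qc()].
#' @return Tibble with one row per participant: `participant_id`,
#'   `n_trials_total`, `mean_probe_rt_ms`, `mean_irrelevant_rt_ms`,
#'   `sd_irrelevant_rt_ms`, `cit_effect_ms`, `d_cit`, `error_rate_probe`,
#'   `error_rate_irrelevant`, `error_rate_target`, `nogo_error_count`,
#'   `nogo_error_rate`, `included`, `exclusion_reason`.
#' @examples
#' set.seed(11)
#' cohort <- simulate_cohort(4)
#' summarize_participants(cohort$trials)
#' @export
summarize_participants <- function(trials, design = design_spec(),
                                   count_omissions = TRUE) {
  qc <- participant_qc(trials, design, count_omissions)
  flt <- filter_trials(trials, design)
  ret <- flt$retained
  press <- ret$response != "none" & !is.na(ret$rt_ms)

  rt_sum <- dplyr::summarise(
    dplyr::group_by(ret[press & ret$stim_type != "nogo", , drop = FALSE],
                    .data$participant_id),
    mean_probe_rt_ms = mean(.data$rt_ms[.data$stim_type == "probe"]),
    mean_irrelevant_rt_ms = mean(.data$rt_ms[.data$stim_type == "irrelevant"]),
    sd_irrelevant_rt_ms = stats::sd(.data$rt_ms[.data$stim_type ==
                                                  "irrelevant"]),
    .groups = "drop"
  )
  nogo_sum <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    nogo_error_count = sum(.data$stim_type == "nogo" & !.data$correct),
    .groups = "drop"
  )
  n_nogo_designed <- design$n_nogo * design$reps_per_block * design$n_blocks

  out <- dplyr::left_join(qc, rt_sum, by = "participant_id")
  out <- dplyr::left_join(out, nogo_sum, by = "participant_id")
  out$nogo_error_rate <- out$nogo_error_count / n_nogo_designed
  out$cit_effect_ms <- out$mean_probe_rt_ms - out$mean_irrelevant_rt_ms
  # a degenerate zero irrelevant-RT SD leaves dCIT undefined (NA) here;
  # compute_dcit() raises the error for callers that require a value
  sd_pos <- !is.na(out$sd_irrelevant_rt_ms) & out$sd_irrelevant_rt_ms > 0
  out$d_cit <- ifelse(sd_pos, out$cit_effect_ms / out$sd_irrelevant_rt_ms,
                      NA_real_)

  undefined <- out$included &
    (is.na(out$mean_probe_rt_ms) | is.na(out$mean_irrelevant_rt_ms))
  if (any(undefined)) {
    stop("no retained probe or irrelevant trials for participant(s): ",
         paste(out$participant_id[undefined], collapse = ", "),
         call. = FALSE)
  }
  dplyr::select(
    out, "participant_id", n_trials_total = "n_trials",
    "mean_probe_rt_ms", "mean_irrelevant_rt_ms", "sd_irrelevant_rt_ms",
    "cit_effect_ms", "d_cit", "error_rate_probe", "error_rate_irrelevant",
    "error_rate_target", "nogo_error_count", "nogo_error_rate",
    "included", "exclusion_reason"
  )
}
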