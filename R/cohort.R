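#' Simulate a full Go/No-go RT-CIT cohort
#'
#' End-to-end generator: draws participant traits, builds a no-repeat trial
#' schedule per participant, simulates responses and latencies, and produces
#' the item-level questionnaire table (26 LSRP + 30 BIS-11 items, under the
#' default item key the first 16 LSRP columns are the primary subscale and the
#' last 10 the secondary) together with the post-test ratings.
#'
#' @param n_participants Cohort size.
#' @param design An [design_spec()].
#' @param config An [trait_model_config()].
#' @return A list of class `rtcit_cohort`: `trials` (one row per stimulus
#'   presentation), `questionnaire` (one row per participant: `lsrp_item_*`,
#'   `bis_item_*`, `rating_*`), and `traits` (the latent generating values,
#'   for calibration checks — not an observable in a real study).
#' @examples
#' set.seed(7)
#' cohort <- simulate_cohort(3)
#' nrow(cohort$trials)  # 3 * 336
#' @export
simulate_cohort <- function(n_participants = 86, design = design_spec(),
                            config = trait_model_config()) {
  traits <- sample_traits(n_participants, config)
  schedules <- lapply(seq_len(n_participants), function(i) {
    generate_schedule(design, traits$participant_id[i])
  })
  trials <- generate_rts(dplyr::bind_rows(schedules), traits, design)

  defs <- default_scale_defs(config)
  primary <- generate_item_responses(traits, defs$lsrp_primary)
  secondary <- generate_item_responses(traits, defs$lsrp_secondary)
  bis <- generate_item_responses(traits, defs$bis)
  lsrp <- cbind(primary, secondary)
  colnames(lsrp) <- sprintf("lsrp_item_%02d", 1:26)
  colnames(bis) <- sprintf("bis_item_%02d", 1:30)

  questionnaire <- dplyr::bind_cols(
    tibble::tibble(participant_id = traits$participant_id),
    tibble::as_tibble(lsrp),
    tibble::as_tibble(bis),
    generate_ratings(traits, config)[, -1]
  )
  structure(list(trials = trials, questionnaire = questionnaire,
                 traits = traits, design = design, config = config),
            class = "rtcit_cohort")
}

#' @export
print.rtcit_cohort <- function(x, ...) {
  cat(sprintf("RT-CIT simulated cohort: %d participants, %d trials\n",
              nrow(x$traits), nrow(x$trials)))
  invisible(x)
}

#' Read / write the trial and questionnaire CSV dialects
#'
#' The trial file has columns `participant_id, block, trial_index, item_id,
#' stim_type, isi_ms, rt_ms, response, correct` with an empty `rt_ms` field
#' when no press occurred; the questionnaire file has one row per participant
#' with `lsrp_item_01..26`, `bis_item_01..30` and `rating_*` columns. Real
#' exports with the same columns are accepted.
#'
#' @param trials,questionnaire Tibbles in the package dialect.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    block = readr::col_integer(),
    trial_index = readr::col_integer(),
    item_id = readr::col_character(),
    stim_type = readr::col_character(),
    isi_ms = readr::col_double(),
    rt_ms = readr::col_double(),
    response = readr::col_character(),
    correct = readr::col_logical()
  ))
}

#' @rdname write_trials_csv
#' @export
write_questionnaire_csv <- function(questionnaire, path) {
  readr::write_csv(questionnaire, path, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_questionnaire_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    .default = readr::col_double()
  ))
}
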