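#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: cohort size, the paradigm
#' design, the trait-model calibration, the master seed, and analysis
#' toggles. All stochastic stages derive their own substream from the single
#' master seed, so toggling one stage does not change another's draws.
#'
#' @param n_participants Cohort size (>= 4 when detection is enabled).
#' @param seed Master seed (integer).
#' @param design An [design_spec()].
#' @param traits An [trait_model_config()].
#' @param n_boot Bootstrap repetitions for [bootstrap_auc()].
#' @param sequential Compute the sequential Bayes-factor trajectory?
#' @param resample_knowledgeable Passed to [bootstrap_auc()].
#' @param count_omissions Passed to [participant_qc()].
#' @param output_dir Directory the report bundle is written to (`NULL` for an
#'   in-memory run).
#' @return An object of class `rtcit_run_config`.
#' @export
run_config <- function(n_participants = 86, seed = 1,
                       design = design_spec(),
                       traits = trait_model_config(),
                       n_boot = 1000, sequential = TRUE,
                       resample_knowledgeable = FALSE,
                       count_omissions = TRUE, output_dir = NULL) {
  if (n_participants < 4) {
    stop("n_participants must be >= 4: the detection stage needs at least 4 ",
         "participants for the naive-SD formula", call. = FALSE)
  }
  stopifnot(inherits(design, "rtcit_design"),
            inherits(traits, "rtcit_trait_config"))
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), design = design, traits = traits,
                 n_boot = as.integer(n_boot), sequential = sequential,
                 resample_knowledgeable = resample_knowledgeable,
                 count_omissions = count_omissions,
                 output_dir = output_dir),
            class = "rtcit_run_config")
}

# independent per-stage substreams derived from the master seed
stage_seeds <- function(seed, stages) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

#' Run the full simulate-preprocess-score-detect-analyze pipeline
#'
#' Simulates a cohort, applies the trial- and participant-level exclusion
#' rules, scores the questionnaires, computes the group-level RT-CIT effect
#' statistics (one-sample t, Cohen's d with CI, JZS Bayes factor), the
#' correlation/Bayes-factor matrix over the preregistered measures, the
#' subjective-ratings contrast, the bootstrap detection efficiency, and
#' (optionally) the sequential Bayes-factor trajectory for the focal
#' association between the RT-CIT effect and secondary psychopathy. When
#' `config$output_dir` is set, writes the CSV/JSON report bundle and a
#' plain-text log there.
#'
#' @param config An [run_config()].
#' @return A list of class `rtcit_run` with elements `cohort`, `summaries`,
#'   `scores`, `exclusions`, `descriptives`, `group_effect`, `ratings_test`,
#'   `cor_matrix`, `detection`, `sequential` and `meta`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(n_participants = 12, seed = 2,
#'                                n_boot = 50, sequential = FALSE))
#' res$group_effect$d
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "rtcit_run_config"))
  seeds <- stage_seeds(config$seed,
                       c("simulate", "detect", "analyze"))

  set.seed(seeds[["simulate"]])
  cohort <- simulate_cohort(config$n_participants, config$design,
                            config$traits)

  flt <- filter_trials(cohort$trials, config$design)
  summaries <- summarize_participants(cohort$trials, config$design,
                                      config$count_omissions)
  included <- summaries[summaries$included, , drop = FALSE]
  scores <- score_questionnaire(cohort$questionnaire)
  ratings <- cohort$questionnaire[, c("participant_id",
                                      grep("^rating_",
                                           names(cohort$questionnaire),
                                           value = TRUE))]

  analysis <- dplyr::inner_join(included, scores, by = "participant_id")
  analysis <- dplyr::inner_join(analysis, ratings, by = "participant_id")

  # group-level RT-CIT effect: one-sample t, d with CI, directional JZS BF
  eff <- analysis$cit_effect_ms
  t_stat <- mean(eff) / (stats::sd(eff) / sqrt(length(eff)))
  d_res <- cohen_d_one_sample(eff)
  bf_eff <- bf_ttest(t_stat, length(eff), alternative = "greater")
  group_effect <- list(mean_ms = mean(eff), sd_ms = stats::sd(eff),
                       t = t_stat, df = length(eff) - 1,
                       p = 2 * stats::pt(-abs(t_stat), length(eff) - 1),
                       d = d_res$d, d_ci = c(d_res$ci_low, d_res$ci_high),
                       bf10 = bf_eff$bf10, n = length(eff))

  # probe vs irrelevant subjective significance
  rt_test <- paired_t(analysis$rating_probe_significance,
                      analysis$rating_irrelevant_significance)
  rt_test$d <- d_from_t(rt_test$t, rt_test$n)
  rt_test$bf10 <- bf_ttest(rt_test$t, rt_test$n,
                           alternative = "greater")$bf10

  measures <- data.frame(
    cit_effect = analysis$cit_effect_ms,
    lsrp_total = analysis$lsrp_total,
    lsrp_primary = analysis$lsrp_primary,
    lsrp_secondary = analysis$lsrp_secondary,
    bis_total = analysis$bis_total,
    nogo_errors = analysis$nogo_error_count
  )
  cor_matrix <- correlation_bf_matrix(measures)
  descriptives <- descriptives_table(measures)

  set.seed(seeds[["detect"]])
  detection <- bootstrap_auc(analysis$d_cit, n_boot = config$n_boot,
                             resample_knowledgeable =
                               config$resample_knowledgeable)

  sequential <- NULL
  if (config$sequential) {
    sequential <- sequential_bf(analysis$cit_effect_ms,
                                analysis$lsrp_secondary)
  }

  meta <- list(seed = config$seed, stage_seeds = as.list(seeds),
               package_version = as.character(utils::packageVersion("rtcit")),
               n_participants = config$n_participants,
               n_included = nrow(included),
               n_trials_per_participant = n_trials_total(config$design),
               n_trials_excluded = nrow(flt$exclusions),
               bonferroni_alpha = bonferroni_alpha(
                 choose(ncol(measures), 2)))

  res <- structure(list(cohort = cohort, summaries = summaries,
                        scores = scores, exclusions = flt$exclusions,
                        descriptives = descriptives,
                        group_effect = group_effect,
                        ratings_test = rt_test, cor_matrix = cor_matrix,
                        detection = detection, sequential = sequential,
                        meta = meta),
                   class = "rtcit_run")
  if (!is.null(config$output_dir)) write_report_bundle(res, config)
  res
}

descriptives_table <- function(measures) {
  tibble::tibble(
    measure = names(measures),
    mean = vapply(measures, mean, numeric(1)),
    sd = vapply(measures, stats::sd, numeric(1)),
    minimum = vapply(measures, min, numeric(1)),
    maximum = vapply(measures, max, numeric(1))
  )
}

#' @export
print.rtcit_run <- function(x, ...) {
  g <- x$group_effect
  cat(sprintf("RT-CIT pipeline run (seed %d): %d simulated, %d included\n",
              x$meta$seed, x$meta$n_participants, x$meta$n_included))
  cat(sprintf(
    "  RT-CIT effect: M = %.2f ms, t(%d) = %.2f, d = %.2f [%.2f, %.2f], BF10 = %.3g\n",
    g$mean_ms, g$df, g$t, g$d, g$d_ci[1], g$d_ci[2], g$bf10))
  cat(sprintf("  detection: mean AUC = %.3f [%.3f, %.3f]\n",
              x$detection$auc_mean, x$detection$ci_low, x$detection$ci_high))
  r_sec <- x$cor_matrix$r["cit_effect", "lsrp_secondary"]
  b <- x$cor_matrix$bf10["cit_effect", "lsrp_secondary"]
  cat(sprintf("  r(CIT effect, secondary LSRP) = %.3f, BF01 = %.3g\n",
              r_sec, 1 / b))
  invisible(x)
}

write_report_bundle <- function(res, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials_csv(res$cohort$trials, file.path(dir, "trials.csv"))
  write_questionnaire_csv(res$cohort$questionnaire,
                          file.path(dir, "questionnaire.csv"))
  readr::write_csv(res$summaries, file.path(dir, "participant_summary.csv"),
                   na = "")
  readr::write_csv(res$exclusions, file.path(dir, "trial_exclusions.csv"))
  readr::write_csv(res$scores, file.path(dir, "scores.csv"))
  readr::write_csv(res$descriptives, file.path(dir, "descriptives.csv"))
  disp <- as.data.frame(res$cor_matrix$display)
  disp <- cbind(measure = rownames(disp), disp)
  readr::write_csv(tibble::as_tibble(disp),
                   file.path(dir, "correlation_bf_matrix.csv"))
  readr::write_csv(tibble::tibble(rep = seq_along(res$detection$auc_reps),
                                  auc = res$detection$auc_reps),
                   file.path(dir, "auc_bootstrap_reps.csv"))
  if (!is.null(res$sequential)) {
    readr::write_csv(res$sequential, file.path(dir, "sequential_bf.csv"))
  }
  summary_json <- list(
    meta = res$meta,
    group_effect = res$group_effect,
    ratings_test = res$ratings_test,
    detection = res$detection[c("auc_mean", "ci_low", "ci_high", "n_boot",
                                "naive_sd", "n_knowledgeable")]
  )
  jsonlite::write_json(summary_json, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("rtcit %s", res$meta$package_version),
    sprintf("master seed: %d", res$meta$seed),
    sprintf("stage seeds: %s",
            paste(names(res$meta$stage_seeds), unlist(res$meta$stage_seeds),
                  sep = "=", collapse = " ")),
    sprintf("participants simulated: %d", res$meta$n_participants),
    sprintf("participants included: %d", res$meta$n_included),
    sprintf("trials per participant: %d", res$meta$n_trials_per_participant),
    sprintf("trials excluded: %d", res$meta$n_trials_excluded)
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Validate trial and questionnaire input files
#'
#' Schema and range checks for the package's CSV dialects: column presence,
#' stimulus-type vocabulary, RT positivity and response-RT consistency for
#' the trial file; Likert range (1-4) and rating ranges for the questionnaire
#' file. Returns the offending rows rather than failing, so callers can
#' inspect real exports before analysis.
#'
#' @param trial_csv,questionnaire_csv File paths (either may be `NULL` to
#'   skip).
#' @return Tibble of violations: `file`, `row`, `column`, `problem`. Zero
#'   rows means both files passed.
#' @export
validate_inputs <- function(trial_csv = NULL, questionnaire_csv = NULL) {
  violations <- list()
  note <- function(file, row, column, problem) {
    tibble::tibble(file = file, row = row, column = column, problem = problem)
  }
  if (!is.null(trial_csv)) {
    if (!file.exists(trial_csv)) stop("cannot read ", trial_csv, call. = FALSE)
    tr <- read_trials_csv(trial_csv)
    need <- c("participant_id", "block", "trial_index", "item_id",
              "stim_type", "isi_ms", "rt_ms", "response", "correct")
    miss <- setdiff(need, names(tr))
    if (length(miss) > 0) {
      violations <- c(violations, list(note(trial_csv, NA_integer_, miss,
                                            "missing column")))
    } else {
      bad <- which(!tr$stim_type %in% c("probe", "irrelevant", "target",
                                        "nogo"))
      if (length(bad)) violations <- c(violations, list(
        note(trial_csv, bad, "stim_type", "unknown stimulus type")))
      bad <- which(!is.na(tr$rt_ms) & tr$rt_ms <= 0)
      if (length(bad)) violations <- c(violations, list(
        note(trial_csv, bad, "rt_ms", "non-positive RT")))
      bad <- which(!tr$response %in% c("familiar", "unfamiliar", "none"))
      if (length(bad)) violations <- c(violations, list(
        note(trial_csv, bad, "response", "unknown response")))
      bad <- which((tr$response == "none") != is.na(tr$rt_ms))
      if (length(bad)) violations <- c(violations, list(
        note(trial_csv, bad, "rt_ms",
             "rt_ms must be present iff a button was pressed")))
    }
  }
  if (!is.null(questionnaire_csv)) {
    if (!file.exists(questionnaire_csv)) {
      stop("cannot read ", questionnaire_csv, call. = FALSE)
    }
    q <- read_questionnaire_csv(questionnaire_csv)
    item_cols <- c(sprintf("lsrp_item_%02d", 1:26),
                   sprintf("bis_item_%02d", 1:30))
    miss <- setdiff(item_cols, names(q))
    if (length(miss) > 0) {
      violations <- c(violations, list(note(questionnaire_csv, NA_integer_,
                                            miss, "missing column")))
    } else {
      for (col in item_cols) {
        bad <- which(is.na(q[[col]]) | !q[[col]] %in% 1:4)
        if (length(bad)) violations <- c(violations, list(
          note(questionnaire_csv, bad, col,
               "Likert response outside 1..4")))
      }
    }
    rating_ranges <- list(rating_probe_significance = c(1, 9),
                          rating_irrelevant_significance = c(1, 9),
                          rating_motivation = c(1, 10),
                          rating_impulsivity = c(1, 10))
    for (col in intersect(names(rating_ranges), names(q))) {
      rg <- rating_ranges[[col]]
      bad <- which(!is.na(q[[col]]) & (q[[col]] < rg[1] | q[[col]] > rg[2]))
      if (length(bad)) violations <- c(violations, list(
        note(questionnaire_csv, bad, col, "rating outside scale range")))
    }
  }
  if (length(violations) == 0) {
    return(tibble::tibble(file = character(), row = integer(),
                          column = character(), problem = character()))
  }
  dplyr::bind_rows(violations)
}
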