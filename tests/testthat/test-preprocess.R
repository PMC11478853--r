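test_that("trial filters exclude for the documented reasons, in order", {
  d <- design_spec()
  trials <- dplyr::bind_rows(
    make_trial(trial_index = 1, rt_ms = 100),                 # too fast
    make_trial(trial_index = 2, rt_ms = 900),                 # too slow
    make_trial(trial_index = 3, stim_type = "probe", rt_ms = 400,
               response = "familiar"),                        # wrong button
    make_trial(trial_index = 4, rt_ms = 400),                 # clean
    make_trial(trial_index = 5, stim_type = "probe", rt_ms = NA,
               response = "none"),                            # omission
    make_trial(trial_index = 6, stim_type = "nogo", rt_ms = 300,
               response = "unfamiliar")                       # commission
  )
  flt <- filter_trials(trials, d)
  expect_equal(flt$exclusions$trial_index, c(1L, 2L, 3L))
  expect_equal(flt$exclusions$reason,
               c("rt_below_min", "rt_above_max", "wrong_button"))
  # omissions and no-go trials pass through untouched
  expect_setequal(flt$retained$trial_index, c(4L, 5L, 6L))
  # a trial that is both too fast and wrong gets the earlier reason
  both <- make_trial(stim_type = "probe", rt_ms = 90, response = "familiar")
  expect_equal(filter_trials(both, d)$exclusions$reason, "rt_below_min")
})

test_that("filtering is idempotent and partitions the input", {
  set.seed(71)
  cohort <- simulate_cohort(4)
  f1 <- filter_trials(cohort$trials)
  expect_equal(nrow(f1$retained) + nrow(f1$exclusions), nrow(cohort$trials))
  f2 <- filter_trials(f1$retained)
  expect_identical(f2$retained, f1$retained)
  expect_equal(nrow(f2$exclusions), 0)
})

test_that("participant-level rules exclude for incomplete or error-heavy data", {
  d <- design_spec()
  clean <- make_clean_session("ok", d)
  expect_true(participant_qc(clean, d)$included)

  short <- clean[-1, ]
  short$participant_id <- "short"
  qc <- participant_qc(short, d)
  expect_false(qc$included)
  expect_equal(qc$exclusion_reason, "incomplete_session")

  # 24 of 48 probe trials in error reaches the 50% rule
  bad <- clean
  bad$participant_id <- "bad"
  probe_rows <- which(bad$stim_type == "probe")[1:24]
  bad$response[probe_rows] <- "familiar"
  bad$correct[probe_rows] <- FALSE
  qc <- participant_qc(bad, d)
  expect_false(qc$included)
  expect_equal(qc$exclusion_reason, "ge50pct_probe_errors")
  expect_equal(qc$error_rate_probe, 0.5)

  # omissions count as errors by default but can be exempted
  omit <- clean
  omit$participant_id <- "omit"
  irr_rows <- which(omit$stim_type == "irrelevant")[1:96]
  omit$response[irr_rows] <- "none"
  omit$rt_ms[irr_rows] <- NA
  omit$correct[irr_rows] <- FALSE
  expect_false(participant_qc(omit, d)$included)
  expect_true(participant_qc(omit, d, count_omissions = FALSE)$included)
})

test_that("incomplete session takes precedence over error rates", {
  d <- design_spec()
  s <- make_clean_session("p", d)[-336, ]
  s$correct[s$stim_type == "probe"] <- FALSE
  s$response[s$stim_type == "probe"] <- "familiar"
  expect_equal(participant_qc(s, d)$exclusion_reason, "incomplete_session")
})

test_that("participant summaries reproduce hand-computed values", {
  d <- design_spec()
  s <- make_clean_session("p1", d)
  probe_rows <- which(s$stim_type == "probe")
  irr_rows <- which(s$stim_type == "irrelevant")
  s$rt_ms[probe_rows] <- rep(c(500, 520), length.out = length(probe_rows))
  s$rt_ms[irr_rows] <- rep(c(440, 460, 480), length.out = length(irr_rows))
  summ <- summarize_participants(s, d)
  expect_equal(summ$mean_probe_rt_ms, 510)
  expect_equal(summ$mean_irrelevant_rt_ms, 460)
  expect_equal(summ$cit_effect_ms, 50)
  expect_equal(summ$sd_irrelevant_rt_ms,
               sd(rep(c(440, 460, 480), length.out = length(irr_rows))))
  expect_equal(summ$d_cit, 50 / summ$sd_irrelevant_rt_ms)
  expect_equal(summ$nogo_error_count, 0)
  expect_true(summ$included)
})

test_that("identical probe and irrelevant RTs give a zero effect", {
  d <- design_spec()
  s <- make_clean_session("p1", d, rt_go = 450)
  summ <- summarize_participants(s, d)
  expect_equal(summ$cit_effect_ms, 0)
  expect_error(compute_dcit(summ), "zero irrelevant-RT SD")
})

test_that("summary identities hold on simulated cohorts", {
  set.seed(72)
  cohort <- simulate_cohort(6)
  summ <- summarize_participants(cohort$trials)
  inc <- summ[summ$included, ]
  expect_equal(inc$cit_effect_ms,
               inc$mean_probe_rt_ms - inc$mean_irrelevant_rt_ms)
  expect_equal(inc$d_cit * inc$sd_irrelevant_rt_ms, inc$cit_effect_ms)
  expect_true(all(inc$nogo_error_count <= 48))
  expect_equal(inc$nogo_error_rate, inc$nogo_error_count / 48)
  expect_true(all(is.na(summ$exclusion_reason) == summ$included))
})

test_that("violation-free data give identical summaries before and after filtering", {
  d <- design_spec()
  set.seed(73)
  s <- make_clean_session("p1", d)
  go <- s$stim_type != "nogo"
  s$rt_ms[go] <- round(runif(sum(go), 200, 700), 1)
  f <- filter_trials(s, d)
  expect_equal(nrow(f$exclusions), 0)
  expect_identical(summarize_participants(s, d),
                   summarize_participants(f$retained, d))
})

test_that("summaries fail loudly when a participant has no usable go RTs", {
  d <- design_spec()
  s <- make_clean_session("p1", d)
  go <- s$stim_type != "nogo"
  s$response[go] <- "none"
  s$rt_ms[go] <- NA
  s$correct[go] <- FALSE
  # all go trials omitted: excluded by QC, so no error is raised ...
  summ <- summarize_participants(s, d)
  expect_false(summ$included)
  # ... but an included participant with no retained RTs is an error
  expect_error(summarize_participants(s, d, count_omissions = FALSE),
               "no retained probe or irrelevant")
})
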