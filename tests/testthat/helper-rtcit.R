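# shared fixtures and independent oracles, built in code at test time

# brute-force pair-counting AUC (ties half credit) -- the oracle for auc()
auc_brute_force <- function(knowledgeable, naive) {
  s <- 0
  for (a in knowledgeable) {
    for (b in naive) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(knowledgeable) * length(naive))
}

# a single hand-buildable go trial row
make_trial <- function(participant_id = "p1", trial_index = 1L,
                       stim_type = "irrelevant", rt_ms = 400,
                       response = NULL, block = 1L,
                       item_id = paste0(stim_type, "_1"), isi_ms = 500) {
  if (is.null(response)) {
    response <- if (is.na(rt_ms)) {
      "none"
    } else if (stim_type == "target") "familiar" else "unfamiliar"
  }
  tibble::tibble(
    participant_id = participant_id, block = as.integer(block),
    trial_index = as.integer(trial_index), item_id = item_id,
    stim_type = stim_type, isi_ms = isi_ms,
    rt_ms = if (response == "none") NA_real_ else rt_ms,
    response = response,
    correct = (stim_type %in% c("probe", "irrelevant") &
                 response == "unfamiliar") |
      (stim_type == "target" & response == "familiar") |
      (stim_type == "nogo" & response == "none")
  )
}

# a complete clean session for one participant: every go press correct and
# inside the RT window, every no-go withheld
make_clean_session <- function(participant_id = "p1",
                               design = design_spec(), rt_go = 400) {
  sched <- generate_schedule(design, participant_id)
  is_go <- sched$stim_type != "nogo"
  sched$rt_ms <- ifelse(is_go, rt_go, NA_real_)
  sched$response <- ifelse(!is_go, "none",
                           ifelse(sched$stim_type == "target", "familiar",
                                  "unfamiliar"))
  sched$correct <- TRUE
  sched
}

# traits row with everything pinned, for deterministic RT-model tests
make_fixed_traits <- function(participant_id = "p1", mu = 430, sigma = 50,
                              tau = 50, probe_shift = 50, target_shift = 50,
                              commission = 0.3, error_go = 0) {
  tibble::tibble(
    participant_id = participant_id,
    z_primary = 0, z_secondary = 0, z_impulsivity = 0, z_inhibition = 0,
    base_mu_ms = mu, base_sigma_ms = sigma, base_tau_ms = tau,
    probe_shift_ms = probe_shift, target_shift_ms = target_shift,
    commission_prob = commission, error_prob_go = error_go
  )
}

count_adjacent_repeats <- function(item_ids) {
  sum(item_ids[-1] == item_ids[-length(item_ids)])
}
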