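#' Go/No-go RT-CIT design parameters
#'
#' Structural constants of the multiple-probes Go/No-go RT-CIT paradigm:
#' item-set composition, presentation schedule and timing. The defaults
#' describe a session of 4 blocks in which 14 distinct items (2 probes,
#' 8 irrelevants, 2 targets, 2 no-go) each appear 6 times per block
#' (84 trials per block, 336 in total), with a jittered inter-stimulus
#' interval, a 1500 ms stimulus window and an 800 ms response deadline.
#'
#' @param n_probes,n_irrelevants,n_targets,n_nogo Number of distinct items of
#'   each stimulus type.
#' @param reps_per_block Presentations of every item within one block.
#' @param n_blocks Number of blocks in the session.
#' @param isi_options_ms Candidate inter-stimulus intervals (ms); one is drawn
#'   uniformly per trial.
#' @param stim_duration_ms Stimulus presentation window (ms); a press later
#'   than this is recorded as no response.
#' @param deadline_ms Response deadline (ms); presses beyond it are collected
#'   but excluded from RT summaries.
#' @param min_valid_rt_ms Fastest latency (ms) accepted as a genuine response.
#'
#' @return An object of class `rtcit_design` (a validated list of the above).
#' @examples
#' d <- design_spec()
#' n_trials_total(d)
#' @export
design_spec <- function(n_probes = 2, n_irrelevants = 8, n_targets = 2,
                        n_nogo = 2, reps_per_block = 6, n_blocks = 4,
                        isi_options_ms = c(250, 500, 750),
                        stim_duration_ms = 1500, deadline_ms = 800,
                        min_valid_rt_ms = 150) {
  d <- list(
    n_probes = as.integer(n_probes),
    n_irrelevants = as.integer(n_irrelevants),
    n_targets = as.integer(n_targets),
    n_nogo = as.integer(n_nogo),
    reps_per_block = as.integer(reps_per_block),
    n_blocks = as.integer(n_blocks),
    isi_options_ms = as.numeric(isi_options_ms),
    stim_duration_ms = as.numeric(stim_duration_ms),
    deadline_ms = as.numeric(deadline_ms),
    min_valid_rt_ms = as.numeric(min_valid_rt_ms)
  )
  class(d) <- "rtcit_design"
  validate_design(d)
  d
}

validate_design <- function(d) {
  counts <- c(d$n_probes, d$n_irrelevants, d$n_targets, d$n_nogo)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("design must contain at least one item", call. = FALSE)
  }
  if (d$reps_per_block < 1 || d$n_blocks < 1) {
    stop("reps_per_block and n_blocks must be positive", call. = FALSE)
  }
  if (length(d$isi_options_ms) == 0 || any(d$isi_options_ms <= 0)) {
    stop("isi_options_ms must be a non-empty set of positive durations",
         call. = FALSE)
  }
  if (d$stim_duration_ms <= 0 || d$deadline_ms <= 0 || d$min_valid_rt_ms <= 0) {
    stop("all durations must be strictly positive", call. = FALSE)
  }
  invisible(d)
}

#' @rdname design_spec
#' @param design An `rtcit_design` object.
#' @export
n_items_total <- function(design) {
  design$n_probes + design$n_irrelevants + design$n_targets + design$n_nogo
}

#' @rdname design_spec
#' @export
n_trials_per_block <- function(design) {
  n_items_total(design) * design$reps_per_block
}

#' @rdname design_spec
#' @export
n_trials_total <- function(design) {
  n_trials_per_block(design) * design$n_blocks
}

#' @export
print.rtcit_design <- function(x, ...) {
  cat("Go/No-go RT-CIT design\n")
  cat(sprintf("  items: %d probes, %d irrelevants, %d targets, %d no-go\n",
              x$n_probes, x$n_irrelevants, x$n_targets, x$n_nogo))
  cat(sprintf("  schedule: %d reps/block x %d blocks = %d trials (%d per block)\n",
              x$reps_per_block, x$n_blocks, n_trials_total(x),
              n_trials_per_block(x)))
  cat(sprintf("  timing: stimulus %g ms, deadline %g ms, ISI {%s} ms\n",
              x$stim_duration_ms, x$deadline_ms,
              paste(x$isi_options_ms, collapse = ", ")))
  invisible(x)
}

# item labels and their stimulus types for a design
design_items <- function(design) {
  tibble::tibble(
    item_id = c(sprintf("probe_%d", seq_len(design$n_probes)),
                sprintf("irrelevant_%d", seq_len(design$n_irrelevants)),
                sprintf("target_%d", seq_len(design$n_targets)),
                sprintf("nogo_%d", seq_len(design$n_nogo))),
    stim_type = rep(c("probe", "irrelevant", "target", "nogo"),
                    times = c(design$n_probes, design$n_irrelevants,
                              design$n_targets, design$n_nogo))
  )
}
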