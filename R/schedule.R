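#' Generate a trial schedule without immediate item repetitions
#'
#' Builds the ordered presentation list for one participant: within every
#' block each item appears exactly `reps_per_block` times, in an order that
#' never shows the same item on two consecutive trials. The no-repeat rule is
#' enforced across block boundaries as well, treating the session as one
#' continuous stream. Each trial receives an inter-stimulus interval drawn
#' uniformly from `design$isi_options_ms`.
#'
#' Ordering is obtained by shuffling each block and then repairing any
#' adjacent repeats by swapping the offending position with a randomly chosen
#' position where neither trial ends up next to its own item; if a bounded
#' number of repair attempts fails the block is reshuffled from scratch.
#'
#' @param design An [design_spec()] object.
#' @param participant_id Identifier stamped on every row.
#' @return A tibble with columns `participant_id`, `block`, `trial_index`
#'   (1-based within the session), `item_id`, `stim_type`, `isi_ms`.
#' @examples
#' sched <- generate_schedule(design_spec(), "p01")
#' nrow(sched) # 336
#' @export
generate_schedule <- function(design, participant_id = "p01") {
  validate_design(design)
  items <- design_items(design)
  k <- nrow(items)
  reps <- design$reps_per_block
  if (k == 1 && reps * design$n_blocks > 1) {
    stop("constraint infeasible: a single item cannot avoid self-repetition",
         call. = FALSE)
  }
  # a no-repeat sequence of multiplicities m exists iff max(m) <= ceiling(L/2)
  if (reps > (k - 1) * reps + 1) {
    stop("constraint infeasible: one item outnumbers all gaps", call. = FALSE)
  }

  blocks <- vector("list", design$n_blocks)
  prev_last <- NA_character_
  for (b in seq_len(design$n_blocks)) {
    blocks[[b]] <- shuffle_no_repeat(rep(items$item_id, each = reps), prev_last)
    prev_last <- blocks[[b]][length(blocks[[b]])]
  }
  seq_items <- unlist(blocks)
  n <- length(seq_items)

  out <- tibble::tibble(
    participant_id = participant_id,
    block = rep(seq_len(design$n_blocks), each = n_trials_per_block(design)),
    trial_index = seq_len(n),
    item_id = seq_items,
    stim_type = items$stim_type[match(seq_items, items$item_id)],
    isi_ms = sample(design$isi_options_ms, n, replace = TRUE)
  )
  out
}

# Shuffle x so that no element equals its predecessor (nor `prev`, for the
# first position). Repair-by-swap with bounded retries, then full reshuffle.
shuffle_no_repeat <- function(x, prev = NA_character_, max_rounds = 50L) {
  n <- length(x)
  if (n <= 1) return(sample(x, n))
  for (round in seq_len(max_rounds)) {
    y <- sample(x, n)
    ok <- FALSE
    for (pass in 1:200) {
      bad <- which(y == c(prev, y[-n]))
      if (length(bad) == 0) { ok <- TRUE; break }
      i <- bad[[1]]
      # candidate positions j where swapping y[i] <-> y[j] breaks the repeat
      # without creating a new one at either site
      j_all <- sample(n)
      swapped <- FALSE
      for (j in j_all) {
        if (j == i) next
        yi <- y[i]; yj <- y[j]
        if (yi == yj) next
        y[i] <- yj; y[j] <- yi
        left_i <- if (i == 1) prev else y[i - 1]
        left_j <- if (j == 1) prev else y[j - 1]
        bad_here <-
          identical(y[i], left_i) ||
          (i < n && y[i + 1] == y[i]) ||
          identical(y[j], left_j) ||
          (j < n && y[j + 1] == y[j])
        if (!bad_here) { swapped <- TRUE; break }
        y[i] <- yi; y[j] <- yj  # undo
      }
      if (!swapped) break  # stuck: reshuffle
    }
    if (ok) return(y)
  }
  stop("could not build a no-repeat ordering; constraint likely infeasible",
       call. = FALSE)
}
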