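#' Score the LSRP questionnaire
#'
#' Sums the 26 four-point Likert items into the primary (16-item, range
#' 16-64) and secondary (10-item, range 10-40) psychopathy subscales and
#' their total (range 26-104). Reverse-keyed items are mapped `x -> 5 - x`
#' before summation. The published reverse-key map is instrument-specific and
#' must be supplied for real data; the default key has no reversals and
#' assigns items 1-16 to the primary and 17-26 to the secondary subscale,
#' matching the package's synthetic questionnaire layout (the generator emits
#' already-oriented items).
#'
#' @param items Numeric vector (one participant) or matrix/data frame
#'   (participants x 26) of responses in 1..4.
#' @param key List with integer vectors `primary` (16 item indices),
#'   `secondary` (10 item indices) and `reverse` (possibly empty).
#' @return Tibble with `lsrp_primary`, `lsrp_secondary`, `lsrp_total`.
#' @examples
#' score_lsrp(rep(4, 26))  # 64 / 40 / 104
#' @export
score_lsrp <- function(items, key = lsrp_key()) {
  m <- as_item_matrix(items, 26, "LSRP")
  stopifnot(length(key$primary) == 16, length(key$secondary) == 10)
  if (length(intersect(key$primary, key$secondary)) > 0 ||
      !setequal(c(key$primary, key$secondary), 1:26)) {
    stop("LSRP key must partition items 1..26 into 16 primary + 10 secondary",
         call. = FALSE)
  }
  m <- reverse_items(m, key$reverse)
  tibble::tibble(
    lsrp_primary = as.integer(rowSums(m[, key$primary, drop = FALSE])),
    lsrp_secondary = as.integer(rowSums(m[, key$secondary, drop = FALSE])),
    lsrp_total = as.integer(rowSums(m))
  )
}

#' @rdname score_lsrp
#' @param primary,secondary,reverse Item index vectors.
#' @export
lsrp_key <- function(primary = 1:16, secondary = 17:26, reverse = integer()) {
  list(primary = as.integer(primary), secondary = as.integer(secondary),
       reverse = as.integer(reverse))
}

#' Score the BIS-11 questionnaire
#'
#' Sums the 30 four-point Likert items into the BIS-11 total (range 30-120),
#' reverse-keying the supplied items (`x -> 5 - x`) first. As with the LSRP,
#' the default is no reversals (synthetic items are already oriented); real
#' data require the published key.
#'
#' @param items Vector (30 responses) or matrix (participants x 30) in 1..4.
#' @param reverse Integer indices of reverse-keyed items.
#' @return Integer vector of totals.
#' @examples
#' score_bis(rep(2, 30), reverse = 1:5)  # 65
#' @export
score_bis <- function(items, reverse = integer()) {
  m <- as_item_matrix(items, 30, "BIS-11")
  m <- reverse_items(m, reverse)
  as.integer(rowSums(m))
}

as_item_matrix <- function(items, k, label) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1)
  if (ncol(items) != k) {
    stop(label, " requires exactly ", k, " items, got ", ncol(items),
         call. = FALSE)
  }
  if (anyNA(items) || !all(items %in% 1:4)) {
    stop(label, " responses must all lie in {1, 2, 3, 4}; missing values ",
         "are not imputed", call. = FALSE)
  }
  items
}

reverse_items <- function(m, reverse) {
  if (length(reverse) > 0) {
    if (any(reverse < 1 | reverse > ncol(m))) {
      stop("reverse-key indices out of range", call. = FALSE)
    }
    m[, reverse] <- 5L - m[, reverse]
  }
  m
}

#' Score a full questionnaire table
#'
#' Convenience wrapper over [score_lsrp()] and [score_bis()] for the package's
#' questionnaire CSV dialect (`lsrp_item_01..26`, `bis_item_01..30`).
#'
#' @param questionnaire Tibble with `participant_id` and item columns.
#' @param key LSRP key ([lsrp_key()]).
#' @param bis_reverse Reverse-key indices for the BIS-11.
#' @return Tibble: `participant_id`, `lsrp_primary`, `lsrp_secondary`,
#'   `lsrp_total`, `bis_total`.
#' @export
score_questionnaire <- function(questionnaire, key = lsrp_key(),
                                bis_reverse = integer()) {
  lsrp_cols <- sprintf("lsrp_item_%02d", 1:26)
  bis_cols <- sprintf("bis_item_%02d", 1:30)
  missing <- setdiff(c(lsrp_cols, bis_cols), names(questionnaire))
  if (length(missing) > 0) {
    stop("questionnaire lacks columns: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(participant_id = questionnaire$participant_id),
    score_lsrp(as.matrix(questionnaire[, lsrp_cols]), key),
    tibble::tibble(bis_total = score_bis(as.matrix(questionnaire[, bis_cols]),
                                         bis_reverse))
  )
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item set:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / variance(total))`,
#' with sample (n-1) variances.
#'
#' @param item_matrix Numeric matrix or data frame, participants x items
#'   (>= 2 of each).
#' @return Alpha (can be negative for incoherent item sets; 1 for perfectly
#'   parallel items).
#' @examples
#' x <- c(1, 2, 3, 4)
#' cronbach_alpha(cbind(x, x, x))  # 1
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("cronbach_alpha needs at least 2 participants and 2 items",
         call. = FALSE)
  }
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    stop("total score has zero variance; reliability undefined",
         call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
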