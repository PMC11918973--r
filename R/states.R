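#' The daily demand state space
#'
#' A patient-day is in exactly one of 15 states: an integer nursing-demand
#' score from 12 down to 0, `"other"` (staying in another ward or a
#' specialized bed), or `"discharged"` (absorbing). The returned order is the
#' fixed display order used throughout the package: scores descending so the
#' vertical axis of a flow diagram reads high demand at the top, with the two
#' non-score labels below the score axis.
#'
#' @return Character vector of the 15 state labels in display order.
#' @export
#' @examples
#' demand_states()
demand_states <- function() {
  c(as.character(12:0), "other", "discharged")
}

# fixed copy used internally (demand_states() is the public accessor)
.states <- c(as.character(12:0), "other", "discharged")

.state_index <- function(s) {
  i <- match(s, .states)
  if (anyNA(i)) {
    stop("unknown state label(s): ", paste(unique(s[is.na(i)]), collapse = ", "))
  }
  i
}

.score_state <- function(score) as.character(score)

#' Display rank of a state
#'
#' Ranks run 0 (score 12, top of the diagram) through 14 (`"discharged"`,
#' bottom). The mapping is a bijection over the 15 states.
#'
#' @param s Character vector of state labels (see [demand_states()]).
#' @return Integer vector of ranks in `0:14`.
#' @export
#' @examples
#' state_order(c("12", "0", "discharged"))
state_order <- function(s) {
  .state_index(s) - 1L
}

#' Is a state a score state?
#'
#' @param s Character vector of state labels.
#' @return Logical vector: `TRUE` for the 13 score states `"0"`..`"12"`.
#' @export
is_score_state <- function(s) {
  .state_index(s) <= 13L
}

#' Numeric score of a state
#'
#' @param s Character vector of state labels.
#' @return Integer vector: the score for score states, `NA` for `"other"`
#'   and `"discharged"`.
#' @export
state_score <- function(s) {
  i <- .state_index(s)
  ifelse(i <= 13L, 13L - i, NA_integer_)
}

#' Demand band labels
#'
#' @return The six band labels in display order: the four score bands
#'   (low 0-2, medium 3-5, high 6-9, ultra-high 10-12, ordered high to low to
#'   match the score axis) then `"other"` and `"discharged"`.
#' @export
band_levels <- function() {
  c("ultra_high", "high", "medium", "low", "other", "discharged")
}

#' Classify a state into a demand band
#'
#' Scores 0-2 are low, 3-5 medium, 6-9 high, and 10-12 ultra-high; the
#' non-score states map to their own labels, never to a score band. The
#' function is total over the 15 states.
#'
#' @param s Character vector of state labels.
#' @return Character vector of band labels (see [band_levels()]).
#' @export
#' @examples
#' classify_band(c("2", "9", "10", "discharged"))
classify_band <- function(s) {
  score <- state_score(s)
  out <- ifelse(score <= 2, "low",
         ifelse(score <= 5, "medium",
         ifelse(score <= 9, "high", "ultra_high")))
  out[is.na(score)] <- s[is.na(score)]
  out
}

# index sets into the 15-state order, used for banded aggregation
.band_index <- function(band) {
  scores <- switch(band,
    low        = 0:2,
    medium     = 3:5,
    high       = 6:9,
    ultra_high = 10:12,
    stop("not a score band: ", band)
  )
  .state_index(as.character(scores))
}
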