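# Day-indexed transition statistics over the 15-state space: the per-day
# count matrix M(d) (each eligible case contributes exactly one transition),
# its joint proportion P(d) = M(d) / N, and the banded trajectory and
# diversity summaries used for cross-ward comparison.

#' Indicator of occupancy
#'
#' 1 when the trajectory occupies state `state` on day `day`, else 0. For any
#' trajectory and day the indicator sums to 1 over the 15 states (states are
#' exclusive and exhaustive).
#'
#' @param states Character vector: one trajectory (a row of a cohort).
#' @param day Day index within the horizon.
#' @param state A state label.
#' @return 0 or 1.
#' @export
indicator <- function(states, day, state) {
  if (day < 1 || day > length(states)) stop("day out of range")
  as.integer(states[day] == state)
}

#' Per-day transition counts
#'
#' The 15 x 15 matrix whose (i, j) entry counts cases in state i on day `day`
#' and state j on day `day + 1`. Every case contributes exactly once, so the
#' matrix total equals the cohort size; the `"discharged"` row has mass only
#' in the `"discharged"` column.
#'
#' @param cohort A `demand_cohort`.
#' @param day Day index in `1..(horizon - 1)` (a transition needs a successor
#'   day).
#' @return An object of class `transition_counts`: `day`, `counts`
#'   (integer matrix with state dimnames), `n_cases`.
#' @export
transition_counts <- function(cohort, day) {
  stopifnot(inherits(cohort, "demand_cohort"))
  day <- as.integer(day)
  if (day < 1 || day >= cohort$horizon) {
    stop("day must be in 1..", cohort$horizon - 1L,
         " (no successor day exists otherwise)")
  }
  src <- factor(cohort$states[, day], levels = .states)
  tgt <- factor(cohort$states[, day + 1L], levels = .states)
  M <- unclass(table(src, tgt))
  dimnames(M) <- list(.states, .states)
  structure(
    list(day = day, counts = M, n_cases = n_eligible(cohort)),
    class = "transition_counts"
  )
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("<transition_counts> day", x$day, "->", x$day + 1L, ";",
      sum(x$counts), "cases\n")
  invisible(x)
}

#' Per-day transition proportions
#'
#' Elementwise division of the counts by the number of eligible cases, so the
#' entries are joint proportions summing to 1. (The conditional, row-wise
#' normalisation used for forecasting lives in [estimate_kernel()]; the two
#' normalisations answer different questions and are kept apart.)
#'
#' @param counts A `transition_counts` object.
#' @param n_eligible Cohort size; defaults to the size recorded on `counts`.
#' @return An object of class `transition_proportions`: `day`, `proportions`,
#'   `n_eligible`.
#' @export
transition_proportions <- function(counts, n_eligible = counts$n_cases) {
  stopifnot(inherits(counts, "transition_counts"))
  if (is.null(n_eligible) || n_eligible < 1) {
    stop("n_eligible must be a positive count")
  }
  if (sum(counts$counts) > n_eligible) {
    stop("matrix total exceeds n_eligible")
  }
  structure(
    list(day = counts$day, proportions = counts$counts / n_eligible,
         n_eligible = n_eligible),
    class = "transition_proportions"
  )
}

#' Round a proportion to a percentage, half up
#'
#' Multiplies by 100 and rounds half up to one decimal — the convention that
#' reproduces printed clinical tables (e.g. 265/684 -> 38.7, 8/839 -> 1.0,
#' 5/994 -> 0.5), unlike round-half-even.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector of percentages with one decimal.
#' @export
#' @examples
#' percent_round(265 / 684)
percent_round <- function(p) {
  floor(p * 1000 + 0.5 + 1e-9) / 10
}

#' Format a proportion as a percentage string
#'
#' @param p Numeric vector of proportions.
#' @return Character vector like `"38.7%"`.
#' @export
format_percent <- function(p) {
  sprintf("%.1f%%", percent_round(p))
}

# the five named band-trajectory categories
.band_categories <- c("low_low", "medium_medium", "high_high",
                      "ultra_high_ultra_high", "zero_discharged")

#' Band-trajectory summary from a count matrix
#'
#' Aggregates a 15 x 15 transition count matrix into the five named
#' trajectory categories — within-band persistence for each of the four score
#' bands, plus the score-0-to-discharge path — and a residual covering all
#' other paths. The 0-to-discharge category uses source state exactly score 0
#' (not the whole low band), and a case discharged on both days falls in the
#' residual, not in any named category; category counts plus the residual
#' therefore partition the cohort.
#'
#' @param counts 15 x 15 count matrix (state order of [demand_states()]).
#' @param n_eligible Cohort size used for shares.
#' @param day Optional day index recorded on the result.
#' @return A tibble `category`, `count`, `share_pct` (one decimal, round half
#'   up), the residual last; attributes `day` and `n_eligible`.
#' @export
#' @examples
#' M <- matrix(0L, 15, 15, dimnames = list(demand_states(), demand_states()))
#' M["7", "6"] <- 265L
#' band_summary_from_counts(M, n_eligible = 684)
band_summary_from_counts <- function(counts, n_eligible, day = NA_integer_) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(15L, 15L)))
  cnt <- c(
    low_low = sum(counts[.band_index("low"), .band_index("low")]),
    medium_medium = sum(counts[.band_index("medium"), .band_index("medium")]),
    high_high = sum(counts[.band_index("high"), .band_index("high")]),
    ultra_high_ultra_high =
      sum(counts[.band_index("ultra_high"), .band_index("ultra_high")]),
    zero_discharged = counts[.state_index("0"), .state_index("discharged")]
  )
  residual <- sum(counts) - sum(cnt)
  out <- tibble::tibble(
    category = c(.band_categories, "other_paths"),
    count = as.integer(unname(c(cnt, residual))),
    share_pct = unname(percent_round(c(cnt, residual) / n_eligible))
  )
  attr(out, "day") <- day
  attr(out, "n_eligible") <- n_eligible
  out
}

#' Band-trajectory summary of a cohort at one day pair
#'
#' @param cohort A `demand_cohort`.
#' @param day Day index in `1..(horizon - 1)`.
#' @return See [band_summary_from_counts()].
#' @export
band_transition_summary <- function(cohort, day) {
  tc <- transition_counts(cohort, day)
  band_summary_from_counts(tc$counts, n_eligible = tc$n_cases, day = tc$day)
}

#' Trajectory diversity from a count matrix
#'
#' @param counts 15 x 15 count matrix.
#' @param n_eligible Cohort size used for the top-2 share.
#' @param day Optional day index recorded on the result.
#' @return A list of class `diversity_summary`: `n_observed_transitions`
#'   (distinct nonzero cells), `n_possible` (always 225 = 15^2),
#'   `score_range` (min/max score occupied on either day of the pair),
#'   `top2_categories` and `top2_share_pct` (share of the two largest named
#'   band categories).
#' @export
diversity_from_counts <- function(counts, n_eligible, day = NA_integer_) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(15L, 15L)))
  band <- band_summary_from_counts(counts, n_eligible, day)
  named <- band[band$category != "other_paths", ]
  top2 <- named[order(named$count, decreasing = TRUE), ][1:2, ]
  score_rows <- 1:13
  occupied <- which(rowSums(counts)[score_rows] > 0 |
                    colSums(counts)[score_rows] > 0)
  scores <- 13L - occupied  # state index -> score value
  structure(
    list(
      day = day,
      n_observed_transitions = sum(counts > 0),
      n_possible = 225L,
      score_range = if (length(scores)) range(scores) else c(NA_integer_, NA_integer_),
      top2_categories = top2$category,
      top2_share_pct = percent_round(sum(top2$count) / n_eligible)
    ),
    class = "diversity_summary"
  )
}

#' Trajectory diversity of a cohort at one day pair
#'
#' Counts how many of the 225 possible single-step transitions are actually
#' observed, the score range touched on the day pair, and how concentrated the
#' cohort is in its two largest named band categories.
#'
#' @param cohort A `demand_cohort`.
#' @param day Day index in `1..(horizon - 1)`.
#' @return See [diversity_from_counts()].
#' @export
transition_diversity <- function(cohort, day) {
  tc <- transition_counts(cohort, day)
  diversity_from_counts(tc$counts, n_eligible = tc$n_cases, day = tc$day)
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("<diversity_summary> day", x$day, ":", x$n_observed_transitions, "of",
      x$n_possible, "transitions; scores", x$score_range[1], "-",
      x$score_range[2], "; top-2 share", paste0(x$top2_share_pct, "%"), "\n")
  invisible(x)
}

#' Long-format transition table
#'
#' All per-day transition counts and joint proportions of a cohort in tidy
#' long format, suitable for CSV export.
#'
#' @param cohort A `demand_cohort`.
#' @param days Day indices (default: all day pairs).
#' @return A tibble: `day`, `source_state`, `target_state`, `count`,
#'   `proportion` (nonzero cells only).
#' @export
transition_long <- function(cohort, days = seq_len(cohort$horizon - 1L)) {
  n <- n_eligible(cohort)
  rows <- lapply(days, function(d) {
    M <- transition_counts(cohort, d)$counts
    nz <- which(M > 0, arr.ind = TRUE)
    tibble::tibble(
      day = d,
      source_state = .states[nz[, 1]],
      target_state = .states[nz[, 2]],
      count = as.integer(M[nz]),
      proportion = M[nz] / n
    )
  })
  do.call(rbind, rows)
}
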