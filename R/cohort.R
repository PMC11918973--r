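#' Construct a demand cohort
#'
#' A cohort holds the processed trajectories of all eligible admissions of one
#' ward in one fiscal year: a character matrix with one row per case and 18
#' columns (day 1 = admission day), every entry one of the 15 state labels.
#' Discharge is absorbing: once a row reaches `"discharged"` it stays there.
#'
#' @param states Character matrix, cases x 18 days, entries from
#'   [demand_states()]. Row names (if any) are used as case identifiers.
#' @param ward Ward label.
#' @param fiscal_year Fiscal-year label.
#' @param horizon Number of days per trajectory (18 in the study design).
#' @return An object of class `demand_cohort`.
#' @export
demand_cohort <- function(states, ward = NA_character_,
                          fiscal_year = NA_character_, horizon = 18L) {
  states <- as.matrix(states)
  if (ncol(states) != horizon) {
    stop("trajectories must span exactly ", horizon, " days")
  }
  if (anyNA(states)) {
    stop("cohort trajectories may not contain missing states")
  }
  idx <- matrix(.state_index(states), nrow(states), ncol(states))
  disch <- idx == 15L
  if (nrow(states) > 0 && horizon > 1) {
    for (d in seq_len(horizon - 1L)) {
      if (any(disch[, d] & !disch[, d + 1L])) {
        stop("'discharged' must be absorbing within each trajectory")
      }
    }
  }
  if (is.null(rownames(states)) && nrow(states) > 0) {
    rownames(states) <- sprintf("case-%04d", seq_len(nrow(states)))
  }
  structure(
    list(states = states, ward = ward, fiscal_year = fiscal_year,
         horizon = as.integer(horizon)),
    class = "demand_cohort"
  )
}

#' Number of eligible cases in a cohort
#'
#' @param cohort A `demand_cohort`.
#' @return Integer count of cases.
#' @export
n_eligible <- function(cohort) {
  stopifnot(inherits(cohort, "demand_cohort"))
  nrow(cohort$states)
}

#' @export
print.demand_cohort <- function(x, ...) {
  cat("<demand_cohort>", n_eligible(x), "cases x", x$horizon, "days;",
      "ward:", x$ward, " fiscal year:", x$fiscal_year, "\n")
  invisible(x)
}

#' Write a cohort to CSV
#'
#' One row per case: `case_id`, `ward`, `fiscal_year`, then `day1`..`day18`
#' state columns using the canonical labels (`"0"`..`"12"`, `"other"`,
#' `"discharged"`).
#'
#' @param cohort A `demand_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "demand_cohort"))
  df <- tibble::as_tibble(cohort$states, .name_repair = "minimal")
  names(df) <- paste0("day", seq_len(cohort$horizon))
  df <- tibble::add_column(df,
    case_id = rownames(cohort$states) %||% character(0),
    ward = rep(cohort$ward, nrow(df)),
    fiscal_year = rep(as.character(cohort$fiscal_year), nrow(df)),
    .before = 1
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV file path.
#' @return A `demand_cohort`.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  day_cols <- grep("^day[0-9]+$", names(df), value = TRUE)
  day_cols <- day_cols[order(as.integer(sub("day", "", day_cols)))]
  states <- as.matrix(df[day_cols])
  rownames(states) <- df$case_id
  colnames(states) <- NULL
  demand_cohort(states,
                ward = if (nrow(df)) df$ward[1] else NA_character_,
                fiscal_year = if (nrow(df)) df$fiscal_year[1] else NA_character_,
                horizon = length(day_cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
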