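# Cohort ingest: turn raw patient-day records into complete 18-day processed
# trajectories, apply the study's eligibility rules, and summarize occupancy
# and score levels per day.

#' Process one admission's records into an 18-day trajectory
#'
#' For each day 1..18 after admission (day 1 = admission day):
#' * days after the discharge record's entry date are `"discharged"`
#'   (the discharge day itself retains its recorded state);
#' * days spent in a non-target ward, or in a specialized bed (bed label with
#'   an `SP` prefix) of the target ward, are masked to `"other"` — the
#'   recorded score on such days is deliberately discarded, not missing;
#' * remaining days take the recorded score, or `NA` when the score is absent
#'   (a genuinely missing day, grounds for exclusion downstream).
#'
#' @param records Tibble of raw records belonging to a single
#'   (patient, admission date) case.
#' @param target_ward Ward under analysis.
#' @param horizon Days per trajectory.
#' @return An object of class `processed_case`: `case_id`, `patient_id`,
#'   `admission_date`, `states` (length-`horizon` character vector, `NA` for
#'   missing days), and `target_days` (days spent in a general bed of the
#'   target ward within the horizon).
#' @export
process_case <- function(records, target_ward, horizon = 18L) {
  if (nrow(records) == 0) stop("no records supplied for the case")
  if (length(unique(records$patient_id)) != 1 ||
      length(unique(records$admission_date)) != 1) {
    stop("records must belong to a single (patient, admission) case")
  }
  bad <- !is.na(records$score) & (records$score < 0 | records$score > 12)
  if (any(bad)) {
    stop("invalid record: score outside 0..12 for patient ",
         records$patient_id[1])
  }
  records <- unique(records)
  if (anyDuplicated(records$date)) {
    stop("ambiguous records: conflicting duplicate rows for one day (patient ",
         records$patient_id[1], ")")
  }

  admission <- records$admission_date[1]
  day <- as.integer(records$date - admission) + 1L
  if (any(day < 1)) stop("record dated before the admission date")
  keep <- day >= 1L & day <= horizon
  records <- records[keep, , drop = FALSE]
  day <- day[keep]

  discharge_date <- records$discharge_date[!is.na(records$discharge_date)]
  disc_day <- if (length(discharge_date)) {
    as.integer(discharge_date[1] - admission) + 1L
  } else {
    Inf
  }

  states <- rep(NA_character_, horizon)
  in_other <- records$ward != target_ward | grepl("^SP", records$bed)
  states[day[in_other]] <- "other"
  with_score <- !in_other & !is.na(records$score)
  states[day[with_score]] <- as.character(records$score[with_score])
  after_disc <- seq_len(horizon) > disc_day
  states[after_disc] <- "discharged"

  target_days <- sum(!in_other & day <= horizon)
  structure(
    list(
      case_id = paste(records$patient_id[1], admission, sep = "/"),
      patient_id = records$patient_id[1],
      admission_date = admission,
      states = states,
      target_days = as.integer(target_days)
    ),
    class = "processed_case"
  )
}

#' Process a full record extract into per-case trajectories
#'
#' Each admission date of the same patient is a separate case.
#'
#' @param records Tibble of raw records (possibly many cases).
#' @param target_ward Ward under analysis.
#' @param horizon Days per trajectory.
#' @return List of `processed_case` objects.
#' @export
process_records <- function(records, target_ward, horizon = 18L) {
  key <- paste(records$patient_id, records$admission_date, sep = "/")
  lapply(split(seq_len(nrow(records)), key), function(idx) {
    process_case(records[idx, , drop = FALSE], target_ward, horizon)
  })
}

#' Apply the eligibility rules and assemble a cohort
#'
#' A case is eligible when (checked in this order, the first failing rule is
#' logged): its admission date falls inside the fiscal window; it spends at
#' least one day in a general bed of the target ward within the horizon; and
#' no day of its processed trajectory is missing (a day is missing iff it is
#' neither `"other"` nor `"discharged"` and has no recorded score).
#'
#' @param cases List of `processed_case` objects (see [process_records()]).
#' @param window Length-2 Date vector: admission window, inclusive (see
#'   [fiscal_window()]).
#' @param ward Ward label stored on the cohort.
#' @param fiscal_year Fiscal-year label stored on the cohort.
#' @return A list with elements `cohort` (a [demand_cohort()] whose case count
#'   is the number of eligible cases) and `exclusions` (tibble `case_id`,
#'   `reason`). Every input case lands in exactly one of the two.
#' @export
filter_eligible <- function(cases, window, ward = NA_character_,
                            fiscal_year = NA_character_) {
  reasons <- character(0)
  ids <- character(0)
  keep <- list()
  for (case in cases) {
    reason <- if (case$admission_date < window[1] ||
                  case$admission_date > window[2]) {
      "outside window"
    } else if (case$target_days < 1L) {
      "no target ward day"
    } else if (anyNA(case$states)) {
      "missing score"
    } else {
      NA_character_
    }
    if (is.na(reason)) {
      keep[[length(keep) + 1L]] <- case
    } else {
      ids <- c(ids, case$case_id)
      reasons <- c(reasons, reason)
    }
  }
  horizon <- if (length(cases)) length(cases[[1]]$states) else 18L
  states <- matrix(character(0), 0, horizon)
  if (length(keep)) {
    states <- do.call(rbind, lapply(keep, `[[`, "states"))
    rownames(states) <- vapply(keep, `[[`, character(1), "case_id")
  }
  list(
    cohort = demand_cohort(states, ward = ward, fiscal_year = fiscal_year,
                           horizon = horizon),
    exclusions = tibble::tibble(case_id = ids, reason = reasons)
  )
}

#' Per-day cohort summary
#'
#' For each requested day: the number of cases still inpatient (in a score
#' state or `"other"`; discharged cases are not inpatient), that count as a
#' percentage of the eligible cohort (one decimal, round half up), and the
#' median with first and third quartiles of the scores among cases in a score
#' state that day. Quartiles use linear interpolation between order statistics
#' (R's default quantile definition, type 7); the convention is recorded in the
#' result's `quantile_type` attribute since published tables rarely state one.
#'
#' @param cohort A `demand_cohort`.
#' @param days Integer vector of days (within the horizon).
#' @return A tibble: `day`, `n_inpatient`, `pct_inpatient`, `score_median`,
#'   `score_q1`, `score_q3`.
#' @export
#' @examples
#' coh <- demand_cohort(matrix("0", 4, 18))
#' summarize_cohort(coh, days = c(1, 10, 18))
summarize_cohort <- function(cohort, days = c(1L, 10L, 18L)) {
  stopifnot(inherits(cohort, "demand_cohort"))
  if (n_eligible(cohort) == 0) stop("cohort is empty")
  if (any(days < 1 | days > cohort$horizon)) {
    stop("days must lie within 1..", cohort$horizon)
  }
  n <- n_eligible(cohort)
  rows <- lapply(as.integer(days), function(d) {
    st <- cohort$states[, d]
    inpatient <- st != "discharged"
    scores <- state_score(st[is_score_state(st)])
    q <- if (length(scores)) {
      quantile(scores, c(.25, .5, .75), type = 7, names = FALSE)
    } else {
      rep(NA_real_, 3)
    }
    tibble::tibble(
      day = d,
      n_inpatient = sum(inpatient),
      pct_inpatient = percent_round(sum(inpatient) / n),
      score_median = q[2], score_q1 = q[1], score_q3 = q[3]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "quantile_type") <- 7L
  out
}
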