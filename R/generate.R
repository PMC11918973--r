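# Synthetic raw-record generation: sample complete 18-day trajectories from an
# archetype, then emit one patient-day record per inpatient day in the CSV
# dialect the ingest module reads.

# core sampler over state indices; caller controls the RNG state
.sample_states <- function(archetype, n, horizon = 18L) {
  S <- matrix(NA_integer_, n, horizon)
  S[, 1] <- sample.int(15L, n, replace = TRUE, prob = archetype$initial_dist)
  K <- archetype$kernels
  for (d in seq_len(horizon - 1L)) {
    cur <- S[, d]
    for (i in sort(unique(cur))) {
      idx <- which(cur == i)
      S[idx, d + 1L] <- sample.int(15L, length(idx), replace = TRUE,
                                   prob = K[i, , d])
    }
  }
  S
}

#' Sample complete trajectories from an archetype
#'
#' Draws `n` 18-day state sequences from the archetype's initial distribution
#' and day-indexed kernels. Discharge is absorbing by construction of the
#' kernels. Reproducible: identical `(archetype, n, seed)` give identical
#' output.
#'
#' @param archetype A `ward_archetype` (see [make_archetype()]).
#' @param n Number of trajectories.
#' @param seed Integer seed.
#' @param horizon Days per trajectory.
#' @return Character matrix `n` x `horizon` of state labels.
#' @export
sample_trajectories <- function(archetype, n, seed, horizon = 18L) {
  stopifnot(inherits(archetype, "ward_archetype"), n >= 1)
  set.seed(seed)
  S <- .sample_states(archetype, n, horizon)
  matrix(.states[S], n, horizon)
}

#' Generate raw patient-day records from an archetype
#'
#' Simulates `n` admissions and emits one record per patient-day, mirroring
#' the layout of the hospital extract the analysis expects: `date`,
#' `patient_id`, `admission_date`, `discharge_date`, `ward`, `bed`, `score`.
#' Days in the `"other"` state carry either a non-target ward label or a
#' specialized bed (`SP-` prefix) within the target ward, each with its own
#' recorded score (the ingest step replaces these with the `"other"` label).
#' Once a trajectory reaches `"discharged"`, the discharge date is set to the
#' last inpatient day and no further rows are emitted. With a positive
#' `missing_rate`, in-ward scores are dropped independently per day,
#' exercising the missing-data exclusion rule downstream.
#'
#' Admission dates are drawn uniformly from the fiscal window (April 1 to
#' March 14) so that the 18-day horizon closes before the fiscal year ends.
#'
#' @param archetype A `ward_archetype`.
#' @param n Number of admissions (cases).
#' @param seed Integer seed.
#' @param fiscal_year Fiscal year of admission (April-to-March, labelled by
#'   its starting calendar year).
#' @param target_ward Ward label written on in-ward records; defaults to the
#'   archetype name.
#' @param missing_rate Per-day probability that an in-ward score is missing;
#'   defaults to the archetype's rate.
#' @return A tibble of raw records, one row per patient-day.
#' @export
#' @examples
#' rec <- generate_cohort(make_archetype("cardiology"), n = 5, seed = 42)
#' head(rec)
generate_cohort <- function(archetype, n, seed, fiscal_year = 2017,
                            target_ward = archetype$name,
                            missing_rate = archetype$missing_rate) {
  stopifnot(inherits(archetype, "ward_archetype"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("'n' must be a positive count")
  }
  n <- as.integer(n)
  set.seed(seed)
  S <- .sample_states(archetype, n)
  window <- fiscal_window(fiscal_year)
  window_days <- as.integer(window[2] - window[1]) + 1L
  admission <- window[1] + (sample.int(window_days, n, replace = TRUE) - 1L)
  beds <- sprintf("G-%02d", sample.int(40L, n, replace = TRUE))

  # first discharged day per case (19 = never within horizon)
  first_disc <- apply(S == 15L, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else 19L
  })
  last_day <- pmin(first_disc - 1L, 18L)

  case_idx <- rep.int(seq_len(n), last_day)
  day <- sequence(last_day)
  st <- S[cbind(case_idx, day)]
  is_other <- st == 14L
  score <- ifelse(is_other, NA_integer_, 13L - st)

  ward <- rep(target_ward, length(day))
  bed <- beds[case_idx]
  if (any(is_other)) {
    # half the transfer days go to another ward, half to a specialized bed
    # within the target ward; both are masked to "other" at ingest
    sp <- stats::runif(sum(is_other)) < 0.5
    ward[is_other][!sp] <- "ward-other"
    bed[is_other][!sp] <- "G-99"
    bed[is_other][sp] <- "SP-01"
    score[is_other] <- sample.int(13L, sum(is_other), replace = TRUE) - 1L
  }
  if (missing_rate > 0) {
    drop <- !is_other & stats::runif(length(day)) < missing_rate
    score[drop] <- NA_integer_
  }

  discharge_date <- as.Date(ifelse(first_disc <= 18L,
                                   admission + first_disc - 2L, NA))
  tibble::tibble(
    date = admission[case_idx] + day - 1L,
    patient_id = sprintf("P%05d", case_idx),
    admission_date = admission[case_idx],
    discharge_date = discharge_date[case_idx],
    ward = ward,
    bed = bed,
    score = as.integer(score)
  )
}

#' Fiscal admission window
#'
#' Japanese fiscal years start on April 1; the study windows close on
#' March 14 so that an 18-day horizon starting on the last admission day
#' still ends within the fiscal year (by March 31).
#'
#' @param year Starting calendar year of the fiscal year.
#' @return Date vector of length 2: window start and end (inclusive).
#' @export
#' @examples
#' fiscal_window(2017)
fiscal_window <- function(year) {
  year <- as.integer(year)
  c(as.Date(sprintf("%d-04-01", year)), as.Date(sprintf("%d-03-14", year + 1L)))
}

#' Write raw records to CSV
#'
#' ISO-8601 dates; absent fields (no discharge yet, missing score) are empty
#' strings.
#'
#' @param records Tibble of raw records as produced by [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read raw records from CSV
#'
#' @param path CSV file with columns `date`, `patient_id`, `admission_date`,
#'   `discharge_date`, `ward`, `bed`, `score`.
#' @return A tibble of raw records.
#' @export
read_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(),
    patient_id = readr::col_character(),
    admission_date = readr::col_date(),
    discharge_date = readr::col_date(),
    ward = readr::col_character(),
    bed = readr::col_character(),
    score = readr::col_integer()
  ), na = c("", "NA"))
}

#' Read a generator configuration file
#'
#' YAML or JSON (by file extension) with fields `archetype`, `n`, `seed`, and
#' optionally `fiscal_year`, `target_ward`, `missing_rate`.
#'
#' @param path Configuration file path.
#' @return A named list of generator arguments.
#' @export
read_cohort_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("archetype", "n", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Generate raw records from a configuration
#'
#' @param config A list as returned by [read_cohort_config()], or a path to a
#'   configuration file.
#' @return A tibble of raw records (see [generate_cohort()]).
#' @export
generate_from_config <- function(config) {
  if (is.character(config)) config <- read_cohort_config(config)
  arch <- make_archetype(config$archetype)
  args <- list(archetype = arch, n = config$n, seed = config$seed)
  for (f in c("fiscal_year", "target_ward", "missing_rate")) {
    if (!is.null(config[[f]])) args[[f]] <- config[[f]]
  }
  do.call(generate_cohort, args)
}
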