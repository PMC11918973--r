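# Shared fixtures and independent brute-force oracles. The oracles enumerate
# per-case, per-day, never touching the matrix implementations they check.

STATES <- demand_states()

# trajectory built from day-state pairs; remaining days repeat the last state
traj <- function(...) {
  s <- c(...)
  stopifnot(length(s) <= 18)
  c(s, rep(s[length(s)], 18 - length(s)))
}

cohort_of <- function(..., ward = "test", fiscal_year = "2017") {
  demand_cohort(do.call(rbind, list(...)), ward = ward, fiscal_year = fiscal_year)
}

# random complete trajectories covering the full state space: random walks
# over the 14 non-absorbed states with a daily discharge hazard
random_cohort <- function(n, seed, p_discharge = 0.12) {
  set.seed(seed)
  states <- matrix(NA_character_, n, 18)
  states[, 1] <- sample(STATES[1:14], n, replace = TRUE)
  for (d in 2:18) {
    for (k in seq_len(n)) {
      prev <- states[k, d - 1]
      states[k, d] <- if (prev == "discharged" || runif(1) < p_discharge) {
        "discharged"
      } else {
        sample(STATES[1:14], 1)
      }
    }
  }
  demand_cohort(states)
}

# oracle: transition counts by explicit per-case enumeration
bf_counts <- function(cohort, d) {
  M <- matrix(0L, 15, 15, dimnames = list(STATES, STATES))
  for (k in seq_len(n_eligible(cohort))) {
    i <- cohort$states[k, d]
    j <- cohort$states[k, d + 1]
    M[i, j] <- M[i, j] + 1L
  }
  M
}

# oracle: band-category counts by per-case classification
bf_band_counts <- function(cohort, d) {
  cats <- c(low_low = 0L, medium_medium = 0L, high_high = 0L,
            ultra_high_ultra_high = 0L, zero_discharged = 0L, other_paths = 0L)
  score_bands <- c("low", "medium", "high", "ultra_high")
  for (k in seq_len(n_eligible(cohort))) {
    src <- cohort$states[k, d]
    tgt <- cohort$states[k, d + 1]
    cat <- if (src == "0" && tgt == "discharged") {
      "zero_discharged"
    } else {
      bs <- classify_band(src)
      bt <- classify_band(tgt)
      if (bs %in% score_bands && bs == bt) paste(bs, bt, sep = "_") else "other_paths"
    }
    cats[cat] <- cats[cat] + 1L
  }
  cats
}

# oracle: distinct observed transitions by per-case set accumulation
bf_n_observed <- function(cohort, d) {
  seen <- character(0)
  for (k in seq_len(n_eligible(cohort))) {
    seen <- union(seen, paste(cohort$states[k, d], cohort$states[k, d + 1]))
  }
  length(seen)
}

# hand-assembled demand kernel for toy chains (fields as documented)
manual_kernel <- function(initial_dist, kernel_list, support = NULL) {
  n_days <- length(kernel_list)
  K <- array(NA_real_, dim = c(15, 15, n_days),
             dimnames = list(STATES, STATES, NULL))
  for (d in seq_len(n_days)) K[, , d] <- kernel_list[[d]]
  if (is.null(support)) {
    support <- matrix(1L, 15, n_days, dimnames = list(STATES, NULL))
  }
  structure(
    list(initial_dist = stats::setNames(initial_dist, STATES), kernels = K,
         support = support, meta = list()),
    class = "demand_kernel"
  )
}

# 15x15 matrix with every state staying put (rows sum to 1)
identity_matrix15 <- function() {
  diag(15)
}

# raw records for one case from a day-state plan:
#  - numeric entries: in-ward day with that score
#  - "other": a day in another ward;  "sp": specialized bed in target ward
#  - "miss": in-ward day with the score absent
#  - "end": discharge after the previous day (no further records)
make_case_records <- function(patient_id, admission, plan,
                              target_ward = "test") {
  admission <- as.Date(admission)
  rows <- list()
  discharge_date <- as.Date(NA)
  for (d in seq_along(plan)) {
    p <- plan[[d]]
    if (identical(p, "end")) {
      discharge_date <- admission + d - 2
      break
    }
    rows[[d]] <- tibble::tibble(
      date = admission + d - 1,
      patient_id = patient_id,
      admission_date = admission,
      ward = if (identical(p, "other")) "ward-b" else target_ward,
      bed = if (identical(p, "sp")) "SP-01" else "G-01",
      score = if (is.numeric(p)) as.integer(p) else NA_integer_
    )
  }
  out <- do.call(rbind, rows)
  out$discharge_date <- discharge_date
  out[, c("date", "patient_id", "admission_date", "discharge_date",
          "ward", "bed", "score")]
}
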