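# Day-inhomogeneous absorbing Markov model of nursing demand: conditional
# (row-normalized) transition kernels per day pair plus a day-1 initial
# distribution. The conditional kernels drive forecasting and simulation;
# the joint proportions of the transition-statistics module are deliberately
# a different normalisation and are kept separate.

.new_demand_kernel <- function(initial_dist, kernels, support, meta = list()) {
  stopifnot(length(initial_dist) == 15L,
            all(dim(kernels)[1:2] == c(15L, 15L)),
            nrow(support) == 15L, ncol(support) == dim(kernels)[3])
  structure(
    list(initial_dist = setNames(as.numeric(initial_dist), .states),
         kernels = kernels, support = support, meta = meta),
    class = "demand_kernel"
  )
}

#' @export
print.demand_kernel <- function(x, ...) {
  n_unobs <- sum(x$support == 0)
  cat("<demand_kernel>", dim(x$kernels)[3], "day kernels over 15 states;",
      n_unobs, "unobserved rows\n")
  invisible(x)
}

#' Estimate the demand kernel of a cohort
#'
#' Row-normalizes the per-day transition counts: the conditional probability
#' of state j on day d+1 given state i on day d is the (i, j) count divided
#' by the row total, wherever the row total is positive. Rows never observed
#' (row total zero) are flagged via the `support` matrix and left as `NA`
#' rather than imputed; the `"discharged"` row is the unit vector on
#' `"discharged"` for every day regardless of support (discharge is absorbing
#' by definition). The day-1 initial distribution is the empirical day-1
#' distribution of the cohort. An optional Laplace pseudocount `alpha` is
#' available for smoothing; the default is purely empirical.
#'
#' @param cohort A `demand_cohort`.
#' @param alpha Laplace pseudocount added to every cell of every observed row
#'   (and used to define all rows when `alpha > 0`). Default 0.
#' @return A `demand_kernel`: `initial_dist` (named length-15 vector),
#'   `kernels` (15 x 15 x (horizon-1) array of conditional probabilities),
#'   `support` (15 x (horizon-1) matrix of row totals), `meta` (ward, fiscal
#'   year, smoothing).
#' @export
estimate_kernel <- function(cohort, alpha = 0) {
  stopifnot(inherits(cohort, "demand_cohort"))
  if (n_eligible(cohort) == 0) stop("cannot estimate a kernel from an empty cohort")
  n_days <- cohort$horizon - 1L
  K <- array(NA_real_, dim = c(15L, 15L, n_days),
             dimnames = list(.states, .states, NULL))
  support <- matrix(0L, 15L, n_days, dimnames = list(.states, NULL))
  for (d in seq_len(n_days)) {
    M <- transition_counts(cohort, d)$counts
    rs <- rowSums(M)
    support[, d] <- as.integer(rs)
    obs <- rs > 0 | alpha > 0
    K[obs, , d] <- (M[obs, , drop = FALSE] + alpha) / (rs[obs] + 15 * alpha)
    # discharge is absorbing whether or not it was reached
    K[15L, , d] <- c(rep(0, 14), 1)
  }
  init <- as.numeric(table(factor(cohort$states[, 1], levels = .states))) /
    n_eligible(cohort)
  .new_demand_kernel(init, K, support,
                     meta = list(ward = cohort$ward,
                                 fiscal_year = cohort$fiscal_year,
                                 alpha = alpha))
}

#' Convert a ward archetype to its true demand kernel
#'
#' The archetype's generating kernels and initial distribution, wrapped as a
#' `demand_kernel`. Every row is fully specified, so the support matrix is 1
#' throughout (equal weight in [compare_kernels()]).
#'
#' @param archetype A `ward_archetype`.
#' @return A `demand_kernel`.
#' @export
as_demand_kernel <- function(archetype) {
  stopifnot(inherits(archetype, "ward_archetype"))
  .new_demand_kernel(
    archetype$initial_dist, archetype$kernels,
    matrix(1L, 15L, dim(archetype$kernels)[3], dimnames = list(.states, NULL)),
    meta = list(ward = archetype$name, source = "archetype")
  )
}

#' Forecast the marginal state distribution at a day
#'
#' Propagates the day-1 initial distribution through the conditional kernels
#' by repeated vector-matrix products. Because discharge is absorbing, its
#' forecast mass is non-decreasing in the day index.
#'
#' @param kernel A `demand_kernel`.
#' @param day Day index in `1..horizon`.
#' @return Named probability vector over the 15 states (sums to 1).
#' @export
forecast_demand <- function(kernel, day) {
  stopifnot(inherits(kernel, "demand_kernel"))
  n_days <- dim(kernel$kernels)[3]
  day <- as.integer(day)
  if (day < 1 || day > n_days + 1L) stop("day must be in 1..", n_days + 1L)
  v <- kernel$initial_dist
  for (d in seq_len(day - 1L)) {
    Kd <- kernel$kernels[, , d]
    reachable <- v > 0
    if (any(reachable & is.na(Kd[, 1]))) {
      stop("forecast reaches an unobserved kernel row at day ", d)
    }
    Kd[is.na(Kd)] <- 0
    v <- as.numeric(v %*% Kd)
  }
  setNames(v, .states)
}

#' Simulate a cohort from a demand kernel
#'
#' Samples `n` complete trajectories from the initial distribution and the
#' day-indexed conditional kernels. If simulation reaches a row that was
#' never observed when the kernel was estimated, behaviour is governed by
#' `unobserved`: `"error"` (default) aborts, `"stay"` substitutes a
#' stay-in-place row.
#'
#' @param kernel A `demand_kernel`.
#' @param n Number of trajectories.
#' @param seed Integer seed; identical `(kernel, n, seed)` give identical
#'   cohorts.
#' @param unobserved `"error"` or `"stay"`.
#' @param ward,fiscal_year Labels stored on the simulated cohort.
#' @return A `demand_cohort` of `n` complete trajectories.
#' @export
simulate_cohort <- function(kernel, n, seed, unobserved = c("error", "stay"),
                            ward = kernel$meta$ward %||% NA_character_,
                            fiscal_year = NA_character_) {
  stopifnot(inherits(kernel, "demand_kernel"), n >= 1)
  unobserved <- match.arg(unobserved)
  n <- as.integer(n)
  n_days <- dim(kernel$kernels)[3]
  set.seed(seed)
  S <- matrix(NA_integer_, n, n_days + 1L)
  S[, 1] <- sample.int(15L, n, replace = TRUE, prob = kernel$initial_dist)
  for (d in seq_len(n_days)) {
    cur <- S[, d]
    for (i in sort(unique(cur))) {
      row <- kernel$kernels[i, , d]
      if (anyNA(row)) {
        if (unobserved == "error") {
          stop("simulation reached the unobserved row for state '",
               .states[i], "' at day ", d,
               "; rerun with unobserved = \"stay\" to substitute a ",
               "stay-in-place row")
        }
        row <- replace(rep(0, 15L), i, 1)
      }
      idx <- which(cur == i)
      S[idx, d + 1L] <- sample.int(15L, length(idx), replace = TRUE, prob = row)
    }
  }
  states <- matrix(.states[S], n, n_days + 1L)
  rownames(states) <- sprintf("sim-%05d", seq_len(n))
  demand_cohort(states, ward = ward, fiscal_year = fiscal_year,
                horizon = n_days + 1L)
}

#' Dissimilarity between two demand kernels
#'
#' Support-weighted mean, over days and states, of the total-variation
#' distance between corresponding conditional rows. Rows unobserved in either
#' kernel are skipped; an observed pair is weighted by the smaller of the two
#' support counts, so well-determined rows dominate. The result is symmetric,
#' lies in `[0, 1]`, and is 0 iff all compared rows are identical.
#'
#' @param a,b `demand_kernel` objects on the same state space and horizon.
#' @return A single dissimilarity value in `[0, 1]`.
#' @export
compare_kernels <- function(a, b) {
  stopifnot(inherits(a, "demand_kernel"), inherits(b, "demand_kernel"))
  if (!all(dim(a$kernels) == dim(b$kernels))) {
    stop("kernels have mismatched dimensions")
  }
  n_days <- dim(a$kernels)[3]
  num <- 0
  den <- 0
  for (d in seq_len(n_days)) {
    both <- a$support[, d] > 0 & b$support[, d] > 0
    for (i in which(both)) {
      w <- min(a$support[i, d], b$support[i, d])
      tv <- 0.5 * sum(abs(a$kernels[i, , d] - b$kernels[i, , d]))
      num <- num + w * tv
      den <- den + w
    }
  }
  if (den == 0) stop("the kernels share no observed rows")
  num / den
}

#' Joint transition entropy at a day pair
#'
#' Shannon entropy (bits) of the joint transition distribution implied by the
#' kernel at day `day`: the forecast occupancy of each state times its
#' conditional row — the distribution that the per-day joint proportion
#' matrix estimates. Higher values mean the cohort's day-to-day flows are
#' spread over more, and more evenly weighted, transitions.
#'
#' @param kernel A `demand_kernel`.
#' @param day Day index in `1..(horizon - 1)`.
#' @return Entropy in bits.
#' @export
transition_entropy <- function(kernel, day) {
  n_days <- dim(kernel$kernels)[3]
  if (day < 1 || day > n_days) stop("day must be in 1..", n_days)
  occ <- forecast_demand(kernel, day)
  J <- occ * kernel$kernels[, , day]
  J[is.na(J)] <- 0
  p <- J[J > 0]
  -sum(p * log2(p))
}

#' Serialize a demand kernel to JSON
#'
#' Lossless round-trippable serialization: initial distribution, per-day
#' row-major conditional matrices (`NA` for unobserved rows), support counts,
#' and metadata.
#'
#' @param kernel A `demand_kernel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "demand_kernel"))
  n_days <- dim(kernel$kernels)[3]
  obj <- list(
    states = .states,
    initial_dist = as.numeric(kernel$initial_dist),
    kernels = lapply(seq_len(n_days), function(d) {
      m <- kernel$kernels[, , d]
      lapply(seq_len(15L), function(i) as.numeric(m[i, ]))
    }),
    support = lapply(seq_len(n_days), function(d) as.integer(kernel$support[, d])),
    meta = kernel$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}

#' Read a demand kernel written by [write_kernel()]
#'
#' @param path JSON file path.
#' @return A `demand_kernel`.
#' @export
read_kernel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kd_list <- obj$kernels
  if (is.array(kd_list) && length(dim(kd_list)) == 3) {
    kd_list <- lapply(seq_len(dim(kd_list)[1]), function(d) kd_list[d, , ])
  }
  n_days <- length(kd_list)
  K <- array(NA_real_, dim = c(15L, 15L, n_days),
             dimnames = list(.states, .states, NULL))
  for (d in seq_len(n_days)) {
    kd <- kd_list[[d]]
    if (is.list(kd)) kd <- do.call(rbind, kd)
    K[, , d] <- kd
  }
  sup <- obj$support
  if (is.matrix(sup)) sup <- lapply(seq_len(nrow(sup)), function(d) sup[d, ])
  support <- matrix(0L, 15L, n_days, dimnames = list(.states, NULL))
  for (d in seq_len(n_days)) support[, d] <- as.integer(sup[[d]])
  meta <- as.list(obj$meta)
  .new_demand_kernel(obj$initial_dist, K, support, meta)
}
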