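test_that("kernel rows are the row-normalized transition counts", {
  # day-1 counts from score 0: three stay, one moves to score 1
  coh <- cohort_of(traj("0", "0"), traj("0", "0"), traj("0", "0"),
                   traj("0", "1"))
  ker <- estimate_kernel(coh)
  expect_equal(ker$kernels["0", "0", 1], 0.75)
  expect_equal(ker$kernels["0", "1", 1], 0.25)
  expect_identical(unname(ker$support["0", 1]), 4L)
  # unobserved rows are flagged, not imputed
  expect_identical(unname(ker$support["5", 1]), 0L)
  expect_true(anyNA(ker$kernels["5", , 1]))
  # discharged row is absorbing for every day regardless of support
  expect_true(all(ker$kernels["discharged", "discharged", ] == 1))
  expect_error(estimate_kernel(demand_cohort(matrix(character(0), 0, 18))),
               "empty")
})

test_that("a deterministic cohort yields a unit kernel row", {
  coh <- do.call(cohort_of, rep(list(traj("0", "1", "1")), 5))
  ker <- estimate_kernel(coh)
  expect_identical(ker$kernels["0", "1", 1], 1)
  expect_identical(unname(ker$initial_dist["0"]), 1)
})

test_that("Laplace smoothing fills all rows and keeps them stochastic", {
  coh <- cohort_of(traj("0", "1"), traj("1", "0"))
  ker <- estimate_kernel(coh, alpha = 0.5)
  expect_false(anyNA(ker$kernels[1:14, , ]))
  rs <- apply(ker$kernels, c(1, 3), sum)
  expect_true(all(abs(rs - 1) < 1e-9))
})

test_that("forecasts match hand-computed marginals on a two-state chain", {
  Q <- identity_matrix15()
  dimnames(Q) <- list(STATES, STATES)
  Q["0", "0"] <- 0.5; Q["0", "1"] <- 0.5
  Q["1", "0"] <- 0.2; Q["1", "1"] <- 0.8
  init <- stats::setNames(c(rep(0, 12), 1, 0, 0), STATES)  # all mass on "0"
  ker <- manual_kernel(init, rep(list(Q), 17))
  expect_identical(forecast_demand(ker, 1), ker$initial_dist)
  d2 <- forecast_demand(ker, 2)
  expect_equal(unname(d2[c("0", "1")]), c(0.5, 0.5))
  d3 <- forecast_demand(ker, 3)
  # 0.5*0.5 + 0.5*0.2 = 0.35 ;  0.5*0.5 + 0.5*0.8 = 0.65
  expect_equal(unname(d3[c("0", "1")]), c(0.35, 0.65))
  expect_error(forecast_demand(ker, 19), "day must be")
})

test_that("forecasts equal exhaustive path enumeration on a small chain", {
  # three states, probabilities exactly representable in binary
  Q1 <- identity_matrix15(); dimnames(Q1) <- list(STATES, STATES)
  Q1["0", "0"] <- 0.5;  Q1["0", "1"] <- 0.5
  Q1["1", "1"] <- 0.75; Q1["1", "2"] <- 0.25
  Q2 <- identity_matrix15(); dimnames(Q2) <- list(STATES, STATES)
  Q2["0", "0"] <- 0;    Q2["0", "2"] <- 1
  Q2["1", "0"] <- 0.5;  Q2["1", "1"] <- 0.5
  init <- stats::setNames(rep(0, 15), STATES)
  init["0"] <- 0.5; init["1"] <- 0.5
  ker <- manual_kernel(init, list(Q1, Q2))

  # oracle: enumerate every day-1..day-3 path and accumulate its probability
  marg <- stats::setNames(rep(0, 15), STATES)
  for (a in STATES) for (b in STATES) for (c in STATES) {
    p <- init[a] * Q1[a, b] * Q2[b, c]
    marg[c] <- marg[c] + p
  }
  expect_equal(forecast_demand(ker, 3), marg)
})

test_that("forecast discharge mass is non-decreasing in the day", {
  for (name in c("orthopaedic", "neurosurgery", "cardiology")) {
    ker <- as_demand_kernel(make_archetype(name))
    disch <- vapply(1:18, function(d) forecast_demand(ker, d)[["discharged"]],
                    numeric(1))
    expect_true(all(diff(disch) >= -1e-12))
  }
})

test_that("simulation is reproducible and respects identity kernels", {
  init <- stats::setNames(rep(0, 15), STATES)
  init[c("3", "8", "other")] <- c(0.4, 0.4, 0.2)
  ker <- manual_kernel(init, rep(list({
    Q <- identity_matrix15(); dimnames(Q) <- list(STATES, STATES); Q
  }), 17))
  coh <- simulate_cohort(ker, 50, seed = 2)
  expect_true(all(coh$states == coh$states[, 1]))
  expect_identical(simulate_cohort(ker, 50, seed = 2)$states, coh$states)
  expect_false(identical(simulate_cohort(ker, 50, seed = 3)$states, coh$states))
})

test_that("reachable unobserved rows stop simulation unless a fallback is on", {
  Q <- identity_matrix15(); dimnames(Q) <- list(STATES, STATES)
  Q["0", "0"] <- 0; Q["0", "5"] <- 1        # day 1 pushes everyone to "5"
  Qna <- Q; Qna["5", ] <- NA_real_          # ... whose next row is unobserved
  init <- stats::setNames(c(rep(0, 12), 1, 0, 0), STATES)
  support <- matrix(1L, 15, 17, dimnames = list(STATES, NULL))
  support["5", 2] <- 0L
  ker <- manual_kernel(init, c(list(Q), list(Qna), rep(list(Q), 15)), support)
  expect_error(simulate_cohort(ker, 10, seed = 1), "unobserved row")
  coh <- simulate_cohort(ker, 10, seed = 1, unobserved = "stay")
  expect_true(all(coh$states[, 3] == "5"))
  expect_error(forecast_demand(ker, 3), "unobserved")
})

test_that("kernel estimation recovers the generator as cohorts grow", {
  arch <- make_archetype("orthopaedic")
  mean_tv <- vapply(c(500, 5000), function(n) {
    coh <- demand_cohort(sample_trajectories(arch, n, seed = 17))
    est <- estimate_kernel(coh)
    tvs <- c()
    for (d in 1:17) for (i in 1:15) {
      if (est$support[i, d] > 0) {
        tvs <- c(tvs, 0.5 * sum(abs(est$kernels[i, , d] - arch$kernels[i, , d])))
      }
    }
    mean(tvs)
  }, numeric(1))
  expect_lt(mean_tv[2], mean_tv[1])
})

test_that("kernel dissimilarity is a bounded symmetric comparison", {
  coh_a <- demand_cohort(sample_trajectories(make_archetype("orthopaedic"), 400, 1))
  coh_b <- demand_cohort(sample_trajectories(make_archetype("cardiology"), 400, 1))
  ka <- estimate_kernel(coh_a)
  kb <- estimate_kernel(coh_b)
  expect_identical(compare_kernels(ka, ka), 0)
  d_ab <- compare_kernels(ka, kb)
  expect_identical(d_ab, compare_kernels(kb, ka))
  expect_gte(d_ab, 0)
  expect_lte(d_ab, 1)
})

test_that("deterministic kernels with disjoint targets are maximally distant", {
  shift_kernel <- function(offset) {
    Q <- matrix(0, 15, 15, dimnames = list(STATES, STATES))
    for (i in 1:13) Q[i, ((i + offset - 1) %% 13) + 1] <- 1
    Q["other", "other"] <- 1; Q["discharged", "discharged"] <- 1
    Q
  }
  support <- matrix(0L, 15, 17, dimnames = list(STATES, NULL))
  support[1:13, ] <- 1L                     # compare only the disjoint rows
  init <- stats::setNames(c(rep(1 / 13, 13), 0, 0), STATES)
  a <- manual_kernel(init, rep(list(shift_kernel(0)), 17), support)
  b <- manual_kernel(init, rep(list(shift_kernel(1)), 17), support)
  expect_identical(compare_kernels(a, b), 1)
})

test_that("kernels serialize losslessly to JSON", {
  coh <- demand_cohort(sample_trajectories(make_archetype("neurosurgery"), 200, 5))
  ker <- estimate_kernel(coh)
  path <- withr::local_tempfile(fileext = ".json")
  write_kernel(ker, path)
  back <- read_kernel(path)
  expect_equal(back$initial_dist, ker$initial_dist)
  expect_equal(back$kernels, ker$kernels)
  expect_identical(unname(back$support), unname(ker$support))
})
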