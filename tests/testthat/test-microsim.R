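# Monte Carlo cohort engine and its analytic forward-product oracle.

test_that("a chain sending everyone 1 -> 7 on day 1 gives one ICU day
           and cost c_1", {
  M <- degenerate_matrices(to = 7L)
  costs <- build_state_costs(base_params, "CHG")
  res <- simulate_cohort(M, costs, n_patients = 50, seed = 3)
  expect_equal(res$per_patient$icu_days, rep(1, 50))
  expect_equal(res$per_patient$cost, rep(costs[["state1"]], 50))
  expect_equal(unname(res$ever_counts[7]), 50)
  expect_equal(res$days_to_discharge, 2)
})

test_that("a deterministic self-loop accrues 30 days of state-1 cost and
           never absorbs", {
  M <- identity_matrices()
  costs <- build_state_costs(base_params, "CHG")
  res <- simulate_cohort(M, costs, n_patients = 20, seed = 3)
  expect_equal(res$per_patient$cost, rep(30 * costs[["state1"]], 20))
  expect_equal(res$icu_days, 30)
  expect_true(all(is.na(res$per_patient$absorbed_day)))
})

test_that("the same seed reproduces a cohort bit-identically and
           different seeds do not", {
  set.seed(99)
  M <- random_matrices()
  costs <- build_state_costs(base_params, "CHG")
  a <- simulate_cohort(M, costs, 200, seed = 11, keep_trajectories = TRUE)
  b <- simulate_cohort(M, costs, 200, seed = 11, keep_trajectories = TRUE)
  expect_identical(a, b)
  c <- simulate_cohort(M, costs, 200, seed = 12, keep_trajectories = TRUE)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("simulation does not disturb the caller's RNG stream", {
  M <- degenerate_matrices()
  costs <- build_state_costs(base_params, "CHG")
  set.seed(5)
  u1 <- runif(1)
  set.seed(5)
  invisible(simulate_cohort(M, costs, 10, seed = 1))
  expect_identical(runif(1), u1)
})

test_that("trajectories conserve occupancy and respect absorbing
           permanence", {
  set.seed(21)
  for (i in 1:3) {
    M <- random_matrices()
    costs <- build_state_costs(base_params, "CHG")
    res <- simulate_cohort(M, costs, 300, seed = 30 + i,
                           keep_trajectories = TRUE)
    traj <- res$trajectories
    expect_true(all(traj %in% 1:8))
    # one state per patient-day: counts sum to n on every day
    expect_equal(unname(colSums(apply(traj, 2, tabulate, nbins = 8))),
                 rep(300, 30))
    # once absorbed, always absorbed in the same state
    for (s in 7:8) {
      hit <- traj == s
      entered <- apply(hit, 1, function(z) any(z))
      first <- ifelse(entered, apply(hit, 1, which.max), NA)
      for (p in which(entered)) {
        expect_true(all(traj[p, first[p]:30] == s))
      }
    }
    expect_lte(max(res$per_patient$icu_days), 30)
    expect_lte(res$n_crbsi, res$n_patients)
  }
})

test_that("unvalidated matrices are refused", {
  P <- identity_matrices()$P
  P[1, 1, 4] <- 0.5 # broken row
  M <- structure(list(arm = "CHG", horizon = 30L, P = P),
                 class = "transition_matrices")
  costs <- build_state_costs(base_params, "CHG")
  expect_error(simulate_cohort(M, costs, 10, seed = 1),
               "failed validation")
})

test_that("expected occupancy is a point mass under identity dynamics
           and matches a hand-multiplied two-day product", {
  M <- identity_matrices()
  pi_t <- expected_occupancy(M)
  expect_equal(pi_t[, 1], rep(1, 30))
  expect_equal(rowSums(pi_t), rep(1, 30))

  # two-day toy chain, hand-multiplied
  P <- array(0, dim = c(8, 8, 2))
  P[1, , 1] <- c(0.6, 0.2, 0, 0, 0, 0, 0.15, 0.05)
  P[2, , 1] <- c(0.7, 0.1, 0, 0, 0, 0, 0.1, 0.1)
  for (i in 3:6) P[i, i, 1] <- 1
  P[7, 7, 1] <- 1; P[8, 8, 1] <- 1
  P[, , 2] <- P[, , 1]
  M2 <- transition_matrices(P, "CHG")
  pi_t <- expected_occupancy(M2)
  expect_equal(pi_t[1, ], c(1, 0, 0, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  # day 2 by hand: row 1 of P(1)
  expect_equal(pi_t[2, ], c(0.6, 0.2, 0, 0, 0, 0, 0.15, 0.05),
               ignore_attr = TRUE)
})

test_that("Monte Carlo occupancy and cost agree with the analytic oracle
           for random matrix sets", {
  set.seed(77)
  for (i in 1:3) {
    M <- random_matrices()
    costs <- build_state_costs(base_params, "CHG")
    n <- 20000
    res <- simulate_cohort(M, costs, n, seed = 500 + i,
                           keep_trajectories = TRUE)
    pi_t <- expected_occupancy(M)
    freq <- t(apply(res$trajectories, 2, tabulate, nbins = 8)) / n
    se <- sqrt(pi_t * (1 - pi_t) / n)
    z <- abs(freq - pi_t)[se > 0] / se[se > 0]
    expect_lt(max(z), 4)       # 240 simultaneous binomial cells
    expect_gte(mean(z < 3), 0.99)

    mc_cost <- res$mean_cost
    se_cost <- stats::sd(res$per_patient$cost) / sqrt(n)
    expect_lt(abs(mc_cost - expected_cost(M, costs)), 3 * se_cost)
  }
})

test_that("expected cost of degenerate chains is exact", {
  costs <- build_state_costs(base_params, "CHG")
  expect_equal(expected_cost(degenerate_matrices(to = 7L), costs),
               costs[["state1"]])
  zero <- build_state_costs(cost_parameters(
    c_icu_day = 0, c_dressing_chg = 0, c_dressing_film = 0,
    c_dressing_gauze = 0, c_ct_change = 0, c_crbsi_direct = 0,
    extra_los_crbsi = 0, c_derm_removal = 0, c_derm_dressings = 0,
    c_derm_insertion = 0, wtp = 0
  ), "CHG")
  expect_equal(expected_cost(identity_matrices(), zero), 0)
})

test_that("analytic ever-entry probabilities match simulated frequencies", {
  M <- fixture_matrices("nonCHG")
  s <- expected_summaries(M)
  n <- 20000
  costs <- build_state_costs(base_params, "nonCHG")
  res <- simulate_cohort(M, costs, n, seed = 9)
  sim_per_1000 <- 1000 * res$ever_counts / n
  for (st in paste0("state", 2:8)) {
    p <- s$ever_per_1000[[st]] / 1000
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sim_per_1000[[st]] - s$ever_per_1000[[st]]),
              3 * 1000 * se + 1e-9)
  }
  # ICU days: mean of a bounded variable, compare with its SE
  se_icu <- stats::sd(res$per_patient$icu_days) / sqrt(n)
  expect_lt(abs(res$icu_days - s$icu_days), 3 * se_icu)
})
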