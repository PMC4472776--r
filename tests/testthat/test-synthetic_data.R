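# Competing-hazards generator, calibration, and record generation.

test_that("zero hazards give identity dynamics", {
  p <- hazard_parameters("CHG", h_discharge = rep(0, 3),
                         h_death = rep(0, 3), crbsi_h0 = 0,
                         crbsi_slope = 0, h_derm = 0, h_newct = 0)
  M <- generate_matrices(p)
  # state 1 is inert, so the whole cohort stays put for 30 days
  for (t in 1:30) {
    expect_equal(M$P[1, , t], c(1, rep(0, 7)))
  }
  costs <- build_state_costs(base_params, "CHG")
  res <- simulate_cohort(M, costs, 20, seed = 1)
  expect_equal(unname(res$ever_counts), c(20, rep(0, 7)))
  expect_equal(res$icu_days, 30)
})

test_that("a certain discharge hazard empties the cohort after one day", {
  p <- hazard_parameters("CHG", h_discharge = c(1, 0, 0),
                         h_death = rep(0, 3), crbsi_h0 = 0,
                         crbsi_slope = 0, h_derm = 0, h_newct = 0)
  M <- generate_matrices(p)
  expect_equal(M$P[1, 7, 1], 1)
  s <- expected_summaries(M)
  expect_equal(unname(s$ever_per_1000[["state7"]]), 1000)
  expect_equal(s$icu_days, 1)
})

test_that("generated matrices are valid for random hazard draws and
           encode the generator structure", {
  set.seed(12)
  for (i in 1:10) {
    p <- hazard_parameters(
      "nonCHG",
      h_discharge = runif(3, 0, 0.15), h_death = runif(3, 0, 0.08),
      crbsi_h0 = runif(1, 0, 5e-3), crbsi_slope = runif(1, 0, 2e-4),
      h_derm = runif(1, 0, 5e-3), h_newct = runif(1, 0, 0.1),
      frac_newct = runif(1)
    )
    M <- generate_matrices(p)
    expect_true(validate_matrices(M)$valid)
    # dermatitis lasts one day and always switches to gauze and tape
    expect_equal(M$P[5, 6, ], rep(1, 30))
    # CRBSI states are single-day: no self-loops
    expect_equal(M$P[3, 3, ], rep(0, 30))
    expect_equal(M$P[4, 4, ], rep(0, 30))
    # the CRBSI hazard increases with catheterization time
    h1 <- sum(M$P[1, 3:4, 1])
    h30 <- sum(M$P[1, 3:4, 30])
    expect_gte(h30, h1)
  }
})

test_that("hazards that sum above one are rejected naming the day", {
  expect_error(
    hazard_parameters("CHG", h_discharge = c(0.5, 0.5, 0.9),
                      h_death = c(0.2, 0.2, 0.2)),
    "above 1 on day 16"
  )
  expect_error(hazard_parameters("CHG", crbsi_slope = -1e-4), "slope")
  expect_error(hazard_parameters("CHG", h_derm = 1.2), "\\[0, 1\\]")
})

test_that("the CHG arm's gauze-and-tape rows follow the reference arm", {
  ref <- fixture_hazards("nonCHG")
  chg <- fixture_hazards("CHG")
  M_ref <- generate_matrices(ref)
  M_chg <- generate_matrices(chg, ref_params = ref)
  expect_equal(M_chg$P[6, , ], M_ref$P[6, , ])
})

test_that("shipped fixture matrices validate and hit the occupancy
           targets analytically", {
  targets <- calibration_targets()
  for (arm in c("CHG", "nonCHG")) {
    M <- fixture_matrices(arm)
    expect_true(validate_matrices(M)$valid)
    expect_equal(M$arm, arm)
    tv <- setNames(targets[[arm]], targets$summary)
    s <- expected_summaries(M)
    ever <- s$ever_per_1000
    expect_lt(abs(ever[["state2"]] - tv[["state2"]]), 0.01)
    expect_lt(abs(ever[["state3"]] + ever[["state4"]] -
                    tv[["state3"]] - tv[["state4"]]), 0.01)
    expect_lt(abs(ever[["state5"]] - tv[["state5"]]), 0.01)
    expect_lt(abs(ever[["state7"]] - tv[["discharge"]]), 0.01)
    expect_lt(abs(ever[["state8"]] - tv[["death"]]), 0.01)
    expect_lt(abs(s$icu_days - tv[["icu_days"]]), 0.001)
  }
  # matrices regenerate from the shipped hazard parameters
  ref <- fixture_hazards("nonCHG")
  M2 <- generate_matrices(ref)
  expect_lt(max(abs(M2$P - fixture_matrices("nonCHG")$P)), 1e-9)
})

test_that("the CHG arm shows markedly fewer CRBSI patients than the
           reference arm", {
  s_chg <- expected_summaries(fixture_matrices("CHG"))
  s_ref <- expected_summaries(fixture_matrices("nonCHG"))
  crbsi <- function(s) s$ever_per_1000[["state3"]] +
    s$ever_per_1000[["state4"]]
  expect_lt(abs(crbsi(s_chg) - 3.1), 0.01)
  expect_lt(abs(crbsi(s_ref) - 14.8), 0.01)
  expect_lt(abs(crbsi(s_ref) - crbsi(s_chg) - 11.7), 0.02)
})

test_that("calibration recovers targets generated from known hazards", {
  truth <- hazard_parameters(
    "nonCHG", h_discharge = c(0.06, 0.04, 0.05),
    h_death = c(0.025, 0.02, 0.022),
    crbsi_h0 = 8e-4, crbsi_slope = 8e-5,
    h_derm = 1.5e-3, h_newct = 0.03, frac_newct = 0.6
  )
  s <- expected_summaries(generate_matrices(truth))
  tv <- c(
    state2 = unname(s$ever_per_1000[["state2"]]),
    state3 = unname(s$ever_per_1000[["state3"]]),
    state4 = unname(s$ever_per_1000[["state4"]]),
    state5 = unname(s$ever_per_1000[["state5"]]),
    discharge = unname(s$ever_per_1000[["state7"]]),
    death = unname(s$ever_per_1000[["state8"]]),
    icu_days = s$icu_days
  )
  fit <- calibrate_hazards(tv, "nonCHG", seed = 2, maxit = 800,
                           n_starts = 1)
  rel <- attr(fit, "relative_errors")
  expect_lt(max(rel), 0.01)
  # the optimizer's best-so-far trace never increases
  expect_true(all(diff(attr(fit, "trace")) <= 0))
})

test_that("infeasible calibration targets are rejected", {
  tv <- c(state2 = 250, state3 = 5, state4 = 10, state5 = 12,
          discharge = 700, death = 400, icu_days = 12)
  expect_error(calibrate_hazards(tv, "nonCHG"), "infeasible")
  tv["discharge"] <- -1
  expect_error(calibrate_hazards(tv, "nonCHG"), "non-negative")
})

test_that("record generation emits complete trajectories and an empty
           stream for n = 0", {
  M <- degenerate_matrices(to = 7L)
  r <- generate_records(M, 3, seed = 5)
  expect_equal(nrow(r), 6L)
  expect_equal(r$state, rep(c(1L, 7L), 3))
  expect_equal(r$day, rep(1:2, 3))
  r0 <- generate_records(M, 0, seed = 5)
  expect_equal(nrow(r0), 0L)
  # never-absorbed patients emit all 30 days
  rid <- generate_records(identity_matrices(), 2, seed = 5)
  expect_equal(nrow(rid), 60L)
})

test_that("generated records round-trip through preprocessing unchanged", {
  M <- fixture_matrices("nonCHG")
  r <- generate_records(M, 500, seed = 44)
  out <- preprocess_records(r)
  expect_equal(out[order(out$patient_id, out$day), ]$state,
               r[order(r$patient_id, r$day), ]$state)
})
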