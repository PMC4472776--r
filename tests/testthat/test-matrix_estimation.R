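# Preprocessing rules and transition-matrix estimation from records.

rec <- function(id, days, states, arm = "CHG") {
  data.frame(patient_id = id, arm = arm, day = days, state = states,
             stringsAsFactors = FALSE)
}

test_that("records beyond the horizon are censored", {
  r <- rec(1, 1:35, rep(1L, 35))
  out <- preprocess_records(r, horizon = 30)
  expect_equal(nrow(out), 30L)
  expect_equal(max(out$day), 30L)
})

test_that("a CRBSI within two days of discharge is back-dated to the
           discharge day", {
  # CRBSI flagged the day after discharge
  r <- rec(1, 1:11, c(rep(1L, 9), 7L, 3L))
  out <- preprocess_records(r)
  expect_equal(out$state[out$day == 10], 3L)
  expect_equal(out$state[out$day == 11], 7L)
  expect_equal(nrow(out), 11L)

  # CRBSI flagged two days after discharge (boundary of the window)
  r <- rec(1, c(1:10, 12), c(rep(1L, 9), 7L, 4L))
  out <- preprocess_records(r)
  expect_equal(out$state[out$day == 10], 4L)
  expect_equal(out$state[out$day == 11], 7L)

  # three days after: outside the window, no re-assignment
  r <- rec(1, c(1:10, 13), c(rep(1L, 9), 7L, 3L))
  expect_error(preprocess_records(r), "after absorption")
})

test_that("malformed records are rejected", {
  expect_error(preprocess_records(rec(1, c(1, 1), c(1L, 2L))),
               "duplicate")
  expect_error(preprocess_records(rec(1, 1:2, c(1L, 9L))), "unknown state")
  expect_error(preprocess_records(rec(1, c(0, 1), c(1L, 1L))),
               "days must be integers")
  expect_error(preprocess_records(rec(1, 1:3, c(1L, 8L, 1L))),
               "after absorption")
})

test_that("two patients splitting between staying and discharge give
           p = 0.5 each", {
  r <- rbind(rec(1, 1:2, c(1L, 1L)), rec(2, 1:2, c(1L, 7L)))
  M <- suppressWarnings(estimate_matrices(r, "CHG", horizon = 2))
  expect_equal(M$P[1, 1, 1], 0.5)
  expect_equal(M$P[1, 7, 1], 0.5)
})

test_that("a toy cohort reproduces hand-tallied count ratios", {
  # five hand-written trajectories avoiding the arm-coupled rows (5, 6)
  trajs <- list(
    c(1, 1, 2, 1, 7),
    c(1, 2, 1, 1, 8),
    c(1, 1, 1, 3, 1),
    c(1, 1, 2, 1, 1),
    c(1, 4, 1, 7, 7)
  )
  r <- do.call(rbind, lapply(seq_along(trajs), function(i)
    rec(i, seq_along(trajs[[i]]), as.integer(trajs[[i]]))))
  M <- suppressWarnings(estimate_matrices(r, "CHG", horizon = 5))

  # independent brute-force tally
  tally <- array(0, dim = c(8, 8, 5))
  for (tr in trajs) {
    for (t in seq_len(length(tr) - 1)) {
      tally[tr[t], tr[t + 1], t] <- tally[tr[t], tr[t + 1], t] + 1
    }
  }
  for (t in 1:4) {
    for (i in 1:6) {
      n_i <- sum(tally[i, , t])
      if (n_i > 0) {
        expect_equal(M$P[i, , t], tally[i, , t] / n_i,
                     info = sprintf("day %d, state %d", t, i))
      }
    }
  }
  expect_true(validate_matrices(M)$valid)
})

test_that("single-arm records warn that arm-coupled rules are skipped", {
  r <- rec(1, 1:2, c(1L, 7L))
  expect_warning(estimate_matrices(r, "CHG", horizon = 2), "single arm")
})

test_that("the dermatitis transition is pooled across arms", {
  # CHG: 2 dermatitis patients, one moving to gauze; non-CHG: 2 moving
  # of 2.  Pooled p(5 -> 6) on day 1 = 3/4; the CHG remainder scales.
  r <- rbind(
    rec(1, 1:2, c(5L, 6L), "CHG"),
    rec(2, 1:2, c(5L, 1L), "CHG"),
    rec(3, 1:2, c(5L, 6L), "nonCHG"),
    rec(4, 1:2, c(5L, 6L), "nonCHG"),
    rec(5, 1:2, c(1L, 1L), "CHG"),
    rec(6, 1:2, c(1L, 1L), "nonCHG")
  )
  M <- estimate_matrices(r, "CHG", horizon = 2)
  expect_equal(M$P[5, 6, 1], 0.75)
  expect_equal(M$P[5, 1, 1], 0.25)
  expect_equal(sum(M$P[5, , 1]), 1)
})

test_that("CHG gauze-and-tape rows are taken from the non-CHG arm", {
  r <- rbind(
    rec(1, 1:2, c(6L, 6L), "CHG"),
    rec(2, 1:2, c(6L, 7L), "nonCHG"),
    rec(3, 1:2, c(6L, 7L), "nonCHG"),
    rec(4, 1:2, c(6L, 6L), "nonCHG"),
    rec(5, 1:2, c(1L, 1L), "CHG")
  )
  M <- estimate_matrices(r, "CHG", horizon = 2)
  # non-CHG counts: 2 of 3 to discharge, 1 of 3 stays
  expect_equal(M$P[6, 7, 1], 2 / 3)
  expect_equal(M$P[6, 6, 1], 1 / 3)
})

test_that("empty state-days fall back without inventing transitions", {
  # state 2 occupied on day 1 only; later days must reuse the day-1 row
  r <- rbind(
    rec(1, 1:4, c(2L, 1L, 1L, 1L)),
    rec(2, 1:4, c(2L, 1L, 7L, 7L))
  )
  M <- suppressWarnings(estimate_matrices(r, "CHG", horizon = 4))
  expect_equal(M$P[2, 1, 3], 1) # copied from day 1
  fb <- attr(M, "fallbacks")
  expect_true(any(fb$state == 2 & fb$day == 3))
  # state 4 never observed: self-loop fallback
  expect_equal(M$P[4, 4, 2], 1)
  expect_true(validate_matrices(M)$valid)
})

test_that("estimation round-trips the generating matrices within
           binomial error", {
  M_ref <- fixture_matrices("nonCHG")
  M_chg <- fixture_matrices("CHG")
  n <- 50000
  recs_chg <- generate_records(M_chg, n, seed = 202)
  recs_chg$patient_id <- recs_chg$patient_id + n # keep ids globally unique
  recs <- rbind(generate_records(M_ref, n, seed = 101), recs_chg)
  est <- estimate_matrices(recs, "nonCHG", horizon = 30)
  expect_true(validate_matrices(est)$valid)

  counts <- crbsicea:::transition_counts(
    recs[recs$arm == "nonCHG", ], 30L)
  expect_roundtrip(est$P, M_ref$P, counts)
})
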