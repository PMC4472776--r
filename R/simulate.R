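# Monte Carlo cohort simulation and the analytic forward-product oracle.

# Per-day cumulative-probability matrices for categorical sampling.
cumulative_rows <- function(P) {
  horizon <- dim(P)[3]
  lapply(seq_len(horizon), function(t) {
    cum <- t(apply(P[, , t], 1, cumsum))
    cum[, N_STATES] <- 1 # guard against accumulated fp error
    cum
  })
}

# Trajectory engine: n independent inhomogeneous chains from state 1.
# Day t's matrix governs the t -> t+1 move; absorbed patients stop moving.
# Returns an n x horizon integer matrix of occupied states.
sim_trajectories <- function(cum, n, horizon) {
  traj <- matrix(1L, n, horizon)
  state <- rep.int(1L, n)
  for (t in seq_len(horizon - 1L)) {
    active <- which(state < 7L)
    if (length(active)) {
      rows <- cum[[t]][state[active], , drop = FALSE]
      u <- stats::runif(length(active))
      # column-wise recycling of u: counts cum entries strictly below u
      state[active] <- 1L + as.integer(rowSums(rows < u))
    }
    traj[, t + 1L] <- state
  }
  traj
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's generator afterwards.
with_seed <- function(seed, fn) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            abs(seed) < 2^31)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  fn()
}

#' Simulate one cohort of patients
#'
#' Draws `n_patients` independent trajectories through the daily
#' transition matrices.  Every patient starts day 1 in state 1; each
#' following day's state is drawn from the current state's row of that
#' day's matrix; the simulation stops at the horizon or at absorption
#' (discharge or death).  Each day a transient state (1--6) is occupied
#' charges that state's full daily cost; absorbing states cost nothing.
#' Because the CRBSI states last a single day, their bundled episode cost
#' (treatment plus attributable extra stay) is charged exactly once, on
#' the diagnosis day.
#'
#' @param M A validated `transition_matrices` object.
#' @param costs A `state_costs` vector from [build_state_costs()].
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Explicit RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#' @param keep_trajectories Keep the full `n x horizon` state matrix in
#'   the result (default `FALSE`).
#' @return An object of class `cohort_result`: arm, seed, per-patient
#'   summaries (`cost`, `icu_days`, `crbsi`, `absorbed_day`,
#'   `absorbed_state`), counts of patients ever entering each state
#'   (`ever_counts`), mean days spent in each state (`days_in_state`),
#'   and the headline means (`mean_cost`, `icu_days`,
#'   `days_to_discharge`, `days_to_death`, `n_crbsi`).
#' @export
#' @examples
#' M <- generate_matrices(hazard_parameters("CHG"))
#' costs <- build_state_costs(cost_parameters(), "CHG")
#' res <- simulate_cohort(M, costs, n_patients = 100, seed = 1)
#' res$mean_cost
simulate_cohort <- function(M, costs, n_patients, seed,
                            keep_trajectories = FALSE) {
  stopifnot(inherits(M, "transition_matrices"),
            inherits(costs, "state_costs"),
            n_patients >= 1)
  assert_valid_matrices(M)
  horizon <- M$horizon
  cum <- cumulative_rows(M$P)
  traj <- with_seed(seed, function()
    sim_trajectories(cum, as.integer(n_patients), horizon))
  res <- summarize_trajectories(traj, unclass(costs), M$arm)
  res$seed <- seed
  if (keep_trajectories) res$trajectories <- traj
  res
}

# Shared trajectory -> cohort_result reduction.
summarize_trajectories <- function(traj, cvec, arm) {
  n <- nrow(traj)
  horizon <- ncol(traj)
  cost <- rowSums(matrix(cvec[traj], n, horizon))
  icu_days <- rowSums(traj <= 6L)
  ever <- vapply(seq_len(N_STATES),
                 function(s) rowSums(traj == s) > 0,
                 logical(n))
  if (n == 1L) ever <- matrix(ever, nrow = 1L)
  first_day <- function(s) {
    hit <- traj == s
    any_hit <- rowSums(hit) > 0
    ifelse(any_hit, max.col(hit, ties.method = "first"), NA_integer_)
  }
  d7 <- first_day(7L)
  d8 <- first_day(8L)
  crbsi <- ever[, 3] | ever[, 4]
  per_patient <- data.frame(
    cost = cost, icu_days = icu_days, crbsi = crbsi,
    absorbed_day = ifelse(!is.na(d7), d7, d8),
    absorbed_state = ifelse(!is.na(d7), 7L, ifelse(!is.na(d8), 8L, NA))
  )
  structure(list(
    arm = arm,
    n_patients = n,
    horizon = horizon,
    per_patient = per_patient,
    ever_counts = stats::setNames(colSums(ever), paste0("state", 1:8)),
    days_in_state = stats::setNames(tabulate(traj, N_STATES) / n,
                                    paste0("state", 1:8)),
    mean_cost = mean(cost),
    icu_days = mean(icu_days),
    days_to_discharge = if (any(!is.na(d7))) mean(d7, na.rm = TRUE) else NA,
    days_to_death = if (any(!is.na(d8))) mean(d8, na.rm = TRUE) else NA,
    n_crbsi = sum(crbsi)
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Simulated cohort (", x$arm, " arm): ", x$n_patients,
      " patients, ", x$horizon, " days\n", sep = "")
  cat(sprintf("  mean cost/patient : %0.2f EUR\n", x$mean_cost))
  cat(sprintf("  mean ICU days     : %0.2f\n", x$icu_days))
  cat(sprintf("  CRBSI patients    : %d (%.1f per 1,000)\n",
              x$n_crbsi, 1000 * x$n_crbsi / x$n_patients))
  cat("  ever in state (per 1,000):\n")
  print(round(1000 * x$ever_counts / x$n_patients, 1))
  invisible(x)
}

#' Analytic per-day occupancy distribution
#'
#' Exact forward product: `pi(1)` is a point mass on state 1 and
#' `pi(t + 1) = pi(t) P(t)`.  Serves as the deterministic oracle for the
#' Monte Carlo engine.
#'
#' @param M A validated `transition_matrices` object.
#' @param horizon Days to evolve (default the matrix horizon).
#' @return A `horizon x 8` matrix; row `t` is the state distribution on
#'   day `t` and sums to 1.
#' @export
expected_occupancy <- function(M, horizon = M$horizon) {
  assert_valid_matrices(M)
  stopifnot(horizon <= M$horizon)
  pi_t <- matrix(0, horizon, N_STATES,
                 dimnames = list(NULL, paste0("state", 1:8)))
  pi_t[1, 1] <- 1
  for (t in seq_len(horizon - 1L)) {
    pi_t[t + 1L, ] <- pi_t[t, ] %*% M$P[, , t]
  }
  pi_t
}

#' Expected days spent in each state
#'
#' Column sums of [expected_occupancy()]: the expected number of days a
#' patient occupies each state over the horizon.
#'
#' @inheritParams expected_occupancy
#' @return Named numeric vector of length 8 (days).
#' @export
expected_days_in_state <- function(M, horizon = M$horizon) {
  colSums(expected_occupancy(M, horizon))
}

#' Expected 30-day cost per patient
#'
#' Closed-form twin of the simulated cost accumulation:
#' `sum_t sum_{s=1..6} pi_s(t) c_s`.  Absorbing states carry zero cost,
#' so the full inner product with the state-cost vector is identical.
#'
#' @param M A validated `transition_matrices` object.
#' @param costs A `state_costs` vector.
#' @param horizon Days (default the matrix horizon).
#' @return Expected cost per patient (EUR).
#' @export
expected_cost <- function(M, costs, horizon = M$horizon) {
  stopifnot(inherits(costs, "state_costs"))
  sum(expected_days_in_state(M, horizon) * unclass(costs))
}

#' Analytic cohort summaries
#'
#' Deterministic expectations of the quantities [simulate_cohort()]
#' estimates: the probability of ever entering each state within the
#' horizon (per 1,000 patients), the mean number of ICU days (days in
#' states 1--6), and the mean day of first entry into discharge and death
#' among patients absorbed within the horizon.  Ever-entry probabilities
#' for transient states use the taboo-probability recursion (mass is
#' removed on first entry), so recurrent states are counted once per
#' patient, not once per visit.
#'
#' @param M A validated `transition_matrices` object.
#' @return A list with `ever_per_1000` (length 8), `icu_days`,
#'   `days_to_discharge`, `days_to_death`.
#' @export
expected_summaries <- function(M) {
  pi_t <- expected_occupancy(M)
  horizon <- nrow(pi_t)
  ever <- numeric(N_STATES)
  ever[1] <- 1
  for (s in 2:6) ever[s] <- ever_entry_probability(M$P, s, horizon)
  ever[7] <- pi_t[horizon, 7]
  ever[8] <- pi_t[horizon, 8]
  mean_entry_day <- function(s) {
    inc <- diff(c(0, pi_t[, s])) # entries on each day (state is absorbing)
    if (pi_t[horizon, s] <= 0) return(NA_real_)
    as.numeric(sum(seq_len(horizon) * inc) / pi_t[horizon, s])
  }
  list(
    ever_per_1000 = stats::setNames(1000 * ever, paste0("state", 1:8)),
    icu_days = sum(pi_t[, TRANSIENT_STATES]),
    days_to_discharge = mean_entry_day(7),
    days_to_death = mean_entry_day(8)
  )
}

# P(ever enter state s by the horizon): evolve the never-entered mass,
# deleting whatever flows into s each day.
ever_entry_probability <- function(P, s, horizon) {
  v <- numeric(N_STATES)
  v[1] <- 1
  if (s == 1L) return(1)
  for (t in seq_len(horizon - 1L)) {
    v <- as.numeric(v %*% P[, , t])
    v[s] <- 0
  }
  1 - sum(v)
}
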