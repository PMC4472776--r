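# Shared builders for tests: toy matrix sets, random valid matrix sets,
# and hand-made cohort results.

# Matrices sending everyone from state 1 to `to` on day 1 (identity
# dynamics elsewhere).
degenerate_matrices <- function(to = 7L, horizon = 30L, arm = "CHG") {
  P <- array(0, dim = c(8, 8, horizon))
  for (t in seq_len(horizon)) diag(P[, , t]) <- 1
  P[1, 1, ] <- 0
  P[1, to, ] <- 1
  transition_matrices(P, arm = arm)
}

# Identity dynamics: everyone stays where they start.
identity_matrices <- function(horizon = 30L, arm = "CHG") {
  P <- array(0, dim = c(8, 8, horizon))
  for (t in seq_len(horizon)) diag(P[, , t]) <- 1
  transition_matrices(P, arm = arm)
}

# A random valid matrix set: transient rows are Dirichlet-like draws
# favouring the diagonal (so cohorts survive a while), absorbing rows
# are unit self-loops.
random_matrices <- function(horizon = 30L, arm = "CHG",
                            concentration = 8) {
  P <- array(0, dim = c(8, 8, horizon))
  for (t in seq_len(horizon)) {
    for (i in 1:6) {
      w <- stats::rexp(8)
      w[i] <- w[i] * concentration
      P[i, , t] <- w / sum(w)
    }
    P[7, 7, t] <- 1
    P[8, 8, t] <- 1
  }
  transition_matrices(P, arm = arm)
}

# Minimal cohort_result from per-patient data, for economics tests.
make_cohort <- function(cost, icu_days, crbsi, arm = "CHG") {
  n <- length(cost)
  structure(list(
    arm = arm, n_patients = n, horizon = 30L,
    per_patient = data.frame(cost = cost, icu_days = icu_days,
                             crbsi = crbsi),
    mean_cost = mean(cost),
    icu_days = mean(icu_days),
    n_crbsi = sum(crbsi)
  ), class = "cohort_result")
}

base_params <- cost_parameters()

# Commercial half-up rounding, independent of the package internals.
round_to <- function(x, digits = 0) {
  v <- as.vector(unclass(x), mode = "numeric")
  names(v) <- names(x)
  p <- 10^digits
  floor(v * p + 0.5 + abs(v * p) * 1e-12) / p
}
round_euros <- function(x) round_to(x, 0)

# Round-trip check of estimated vs generating matrices using exact
# binomial two-sided tail probabilities per cell (the normal 3-SE rule
# breaks down for the rare-event cells, whose expected counts are < 5).
# Zero/one-probability cells must be recovered exactly; for the rest we
# bound the worst cell and the bulk of the p-value distribution.
expect_roundtrip <- function(est, truth, counts, min_n = 50) {
  n_it <- apply(counts, c(1, 3), sum)
  pv <- c()
  for (t in seq_len(dim(truth)[3] - 1)) {
    for (i in 1:6) {
      n_i <- n_it[i, t]
      if (n_i < min_n) next
      for (j in 1:8) {
        p <- truth[i, j, t]
        if (p == 0 || p == 1) {
          expect_equal(est[i, j, t], p)
        } else {
          x <- round(est[i, j, t] * n_i)
          pv <- c(pv, min(1, 2 * min(
            stats::pbinom(x, n_i, p),
            stats::pbinom(x - 1, n_i, p, lower.tail = FALSE)
          )))
        }
      }
    }
  }
  expect_gt(length(pv), 100)
  expect_gt(min(pv), 1e-5)        # worst cell over ~500 simultaneous tests
  expect_gte(mean(pv > 0.0027), 0.99) # bulk at the 3-SE-equivalent level
  invisible(pv)
}
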