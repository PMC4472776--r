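# Estimation of daily transition matrices from longitudinal
# patient-day records.

#' Read patient-day records from CSV
#'
#' Schema: `patient_id`, `arm`, `day` (1-based), `state` (1--8), one row
#' per patient-day.
#'
#' @param path CSV path.
#' @return A validated records data.frame sorted by patient and day.
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(d)
}

# Structural validation shared by the estimation entry points.
validate_records <- function(records) {
  need <- c("patient_id", "arm", "day", "state")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  u <- unique(as.character(records$arm))
  records$arm <- vapply(u, match_arm, character(1),
                        USE.NAMES = FALSE)[match(records$arm, u)]
  if (any(records$day < 1) || any(records$day != floor(records$day))) {
    stop("record days must be integers >= 1", call. = FALSE)
  }
  if (any(!(records$state %in% 1:8))) {
    stop("unknown state id in records (states are 1-8)", call. = FALSE)
  }
  key <- paste(records$patient_id, records$day)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, day) rows in records", call. = FALSE)
  }
  records <- records[order(records$patient_id, records$day), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Preprocess patient-day records
#'
#' Applies the model's data-preparation rules before matrix estimation:
#'
#' 1. censoring: days beyond `horizon` are dropped;
#' 2. late-diagnosis back-dating: if a patient is recorded as discharged
#'    (state 7) on day `d` and a CRBSI state (3 or 4) appears within the
#'    two following days, the infection is considered to have occurred on
#'    the day of discharge -- the CRBSI replaces the discharge entry on
#'    day `d`, with discharge following on day `d + 1`;
#' 3. absorbing permanence: once discharged or dead, every later recorded
#'    day must repeat that state.
#'
#' @param records Records data.frame (`patient_id`, `arm`, `day`,
#'   `state`).
#' @param horizon Censoring horizon in days (default 30).
#' @return The preprocessed records data.frame.
#' @export
preprocess_records <- function(records, horizon = 30L) {
  records <- validate_records(records)
  records <- records[records$day <= horizon, , drop = FALSE]
  out <- lapply(split(records, records$patient_id), function(r) {
    r <- r[order(r$day), , drop = FALSE]
    disch <- which(r$state == 7L)
    if (length(disch)) {
      d <- r$day[disch[1L]]
      late <- which(r$state %in% CRBSI_STATES &
                      r$day > d & r$day <= d + 2L)
      if (length(late)) {
        crbsi_state <- r$state[late[1L]]
        r$state[r$day == d] <- crbsi_state
        r <- r[r$day <= d, , drop = FALSE]
        if (d + 1L <= horizon) {
          r <- rbind(r, data.frame(
            patient_id = r$patient_id[1L], arm = r$arm[1L],
            day = d + 1L, state = 7L, stringsAsFactors = FALSE
          ))
        }
      }
    }
    # absorbing permanence
    first_abs <- which(r$state %in% ABSORBING_STATES)
    if (length(first_abs)) {
      a <- first_abs[1L]
      later <- seq_len(nrow(r)) > a
      if (any(r$state[later] != r$state[a])) {
        stop("patient ", r$patient_id[1L],
             ": state changes after absorption (day ",
             r$day[a], ")", call. = FALSE)
      }
    }
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate daily transition matrices from records
#'
#' Maximum-likelihood (count-ratio) estimation:
#' `p_ij(t) = n_ij(t) / n_i(t)`, where `n_i(t)` counts patients in state
#' `i` on day `t` with a recorded day `t + 1`, and `n_ij(t)` those moving
#' to `j`.  Absorbing rows are forced to unit self-loops.  Two
#' arm-coupling rules apply when both arms are present in `records`:
#' the dermatitis-to-gauze probability (5 to 6) is pooled across arms,
#' and the CHG arm's state-6 rows are copied from the non-CHG estimate,
#' since gauze-and-tape patients no longer wear the study dressing.
#'
#' If no patient occupies a transient state on some day, that row falls
#' back to the nearest earlier day with data, then to the time-pooled row
#' for the state, then to a self-loop; fallbacks are recorded in the
#' `fallbacks` attribute.
#'
#' @param records Preprocessed records (see [preprocess_records()]),
#'   ideally containing both arms.
#' @param arm Arm to estimate matrices for.
#' @param horizon Number of daily matrices (default 30).
#' @return A `transition_matrices` object with attribute `fallbacks`.
#' @export
estimate_matrices <- function(records, arm, horizon = 30L) {
  records <- validate_records(records)
  arm <- match_arm(arm)
  both_arms <- all(ARM_LEVELS %in% unique(records$arm))
  if (!both_arms) {
    warning("records contain a single arm: dermatitis pooling and ",
            "gauze-row substitution are skipped", call. = FALSE)
  }

  counts <- transition_counts(records[records$arm == arm, ], horizon)
  est <- estimate_from_counts(counts, horizon)
  P <- est$P

  if (both_arms) {
    other <- setdiff(ARM_LEVELS, arm)
    counts_other <- transition_counts(records[records$arm == other, ],
                                      horizon)
    P <- pool_dermatitis_row(P, counts, counts_other)
    if (arm == "CHG") {
      ref <- estimate_from_counts(counts_other, horizon)
      P[6, , ] <- ref$P[6, , ]
    }
  }

  M <- transition_matrices(P, arm = arm, validate = TRUE)
  attr(M, "fallbacks") <- est$fallbacks
  M
}

# Count-ratio rows plus the empty-row fallback chain, single arm.
estimate_from_counts <- function(counts, horizon) {
  fallbacks <- data.frame(day = integer(), state = integer(),
                          method = character(), stringsAsFactors = FALSE)
  P <- array(0, dim = c(N_STATES, N_STATES, horizon))
  pooled <- apply(counts, c(1, 2), sum) # time-pooled counts per (i, j)
  n_it <- apply(counts, c(1, 3), sum)   # n_i(t)

  for (t in seq_len(horizon)) {
    for (i in TRANSIENT_STATES) {
      if (n_it[i, t] > 0) {
        P[i, , t] <- counts[i, , t] / n_it[i, t]
      } else {
        prev <- which(n_it[i, seq_len(t - 1L)] > 0)
        if (length(prev)) {
          prev <- max(prev)
          P[i, , t] <- counts[i, , prev] / n_it[i, prev]
          method <- sprintf("nearest earlier day (%d)", prev)
        } else if (sum(pooled[i, ]) > 0) {
          P[i, , t] <- pooled[i, ] / sum(pooled[i, ])
          method <- "time-pooled row"
        } else {
          P[i, i, t] <- 1
          method <- "self-loop (state never observed)"
        }
        fallbacks <- rbind(fallbacks, data.frame(
          day = t, state = i, method = method, stringsAsFactors = FALSE
        ))
      }
    }
    for (i in ABSORBING_STATES) P[i, i, t] <- 1
  }
  list(P = P, fallbacks = fallbacks)
}

# n_ij(t) count array (8 x 8 x horizon) from single-arm records.
# Vectorized over consecutive-day row pairs within a patient.
transition_counts <- function(records, horizon) {
  r <- records[order(records$patient_id, records$day), , drop = FALSE]
  n <- nrow(r)
  if (n < 2L) return(array(0L, dim = c(N_STATES, N_STATES, horizon)))
  ok <- r$patient_id[-n] == r$patient_id[-1L] &
    r$day[-1L] - r$day[-n] == 1L &
    r$day[-n] <= horizon
  from <- r$state[-n][ok]
  to <- r$state[-1L][ok]
  day <- r$day[-n][ok]
  idx <- from + (to - 1L) * N_STATES + (day - 1L) * N_STATES^2
  array(tabulate(idx, nbins = N_STATES^2 * horizon),
        dim = c(N_STATES, N_STATES, horizon))
}

# Replace the day-t 5->6 cell by the arms-pooled estimate and rescale the
# rest of row 5 to keep it stochastic.
pool_dermatitis_row <- function(P, counts_arm, counts_other) {
  horizon <- dim(P)[3]
  for (t in seq_len(horizon)) {
    n5 <- sum(counts_arm[5, , t]) + sum(counts_other[5, , t])
    if (n5 == 0) next # fallback row already in place
    p56 <- (counts_arm[5, 6, t] + counts_other[5, 6, t]) / n5
    row <- P[5, , t]
    rest <- sum(row[-6])
    if (rest > 0) {
      row[-6] <- row[-6] * (1 - p56) / rest
    } else {
      row <- rep(0, N_STATES)
      row[5] <- 1 - p56 # degenerate: park remainder in the self-loop
    }
    row[6] <- p56
    P[5, , t] <- row
  }
  P
}
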