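# State space and transition-matrix containers.

#' The eight-state ICU health-state space
#'
#' Returns the model's state table.  States 1--4 cross CRBSI status with
#' the need for a new catheter (CT), state 5 is contact dermatitis, state 6
#' the gauze-and-tape fallback dressing, and states 7 (ICU discharge) and
#' 8 (death) are absorbing.
#'
#' @return A data.frame with columns `id`, `label` and `absorbing`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  data.frame(
    id = 1:8,
    label = c(
      "no CRBSI / no new CT",
      "no CRBSI / new CT",
      "CRBSI / no new CT",
      "CRBSI / new CT",
      "contact dermatitis",
      "gauze-and-tape dressing",
      "discharge",
      "death"
    ),
    absorbing = c(rep(FALSE, 6), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

N_STATES <- 8L
TRANSIENT_STATES <- 1:6
ABSORBING_STATES <- 7:8
CRBSI_STATES <- 3:4

ARM_LEVELS <- c("CHG", "nonCHG")

# Normalise user-supplied arm labels ("chg", "non-CHG", "control", ...).
match_arm <- function(arm) {
  key <- tolower(gsub("[^a-z]", "", tolower(arm)))
  if (key %in% c("chg", "tegaderm", "intervention")) return("CHG")
  if (key %in% c("nonchg", "ref", "reference", "control", "film")) {
    return("nonCHG")
  }
  stop("unknown arm label: ", arm, " (use 'CHG' or 'nonCHG')", call. = FALSE)
}

#' Construct a set of daily transition matrices
#'
#' Bundles one 8 x 8 row-stochastic matrix per model day.  The matrix for
#' day `t` governs the move from day `t` to day `t + 1`; the final day's
#' matrix is carried for completeness but unused by a horizon-limited
#' simulation.
#'
#' @param P An `8 x 8 x horizon` numeric array, or a list of `horizon`
#'   8 x 8 matrices, of daily transition probabilities `p_ij(t)`.
#' @param arm Study arm, `"CHG"` or `"nonCHG"`.
#' @param validate If `TRUE` (default), fail unless [validate_matrices()]
#'   passes.
#' @return An object of class `transition_matrices` with elements `arm`,
#'   `horizon` and `P` (the array).
#' @export
transition_matrices <- function(P, arm, validate = TRUE) {
  if (is.list(P)) {
    P <- array(unlist(P), dim = c(N_STATES, N_STATES, length(P)))
  }
  if (!is.array(P) || length(dim(P)) != 3L ||
      dim(P)[1] != N_STATES || dim(P)[2] != N_STATES) {
    stop("P must be an 8 x 8 x horizon array", call. = FALSE)
  }
  obj <- structure(
    list(arm = match_arm(arm), horizon = dim(P)[3], P = P),
    class = "transition_matrices"
  )
  if (validate) {
    v <- validate_matrices(obj)
    if (!v$valid) {
      stop("invalid transition matrices:\n",
           paste(utils::capture.output(print(v)), collapse = "\n"),
           call. = FALSE)
    }
  }
  obj
}

#' Validate a set of daily transition matrices
#'
#' Checks that every entry lies in \[0, 1\], that every row of every daily
#' matrix sums to 1 (within `tol`), and that the absorbing states 7
#' (discharge) and 8 (death) are unit self-loops on every day.
#'
#' @param M A `transition_matrices` object or a bare `8 x 8 x horizon`
#'   array.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return An object of class `tm_validation`: a list with `valid`
#'   (logical) and `violations`, a data.frame naming each offending
#'   `(day, state)` row and the issue.
#' @export
validate_matrices <- function(M, tol = 1e-9) {
  P <- if (inherits(M, "transition_matrices")) M$P else M
  if (!is.array(P) || length(dim(P)) != 3L ||
      dim(P)[1] != N_STATES || dim(P)[2] != N_STATES) {
    stop("transition matrices must form an 8 x 8 x horizon array",
         call. = FALSE)
  }
  horizon <- dim(P)[3]
  viol <- list()
  add <- function(day, state, issue, value) {
    viol[[length(viol) + 1L]] <<- data.frame(
      day = day, state = state, issue = issue, value = value,
      stringsAsFactors = FALSE
    )
  }
  for (t in seq_len(horizon)) {
    Pt <- P[, , t]
    for (i in seq_len(N_STATES)) {
      row <- Pt[i, ]
      if (anyNA(row)) {
        add(t, i, "missing probability", NA_real_)
        next
      }
      if (any(row < -1e-12) || any(row > 1 + 1e-12)) {
        add(t, i, "entry outside [0, 1]", row[which.max(abs(row - 0.5))])
      }
      s <- sum(row)
      if (abs(s - 1) > tol) add(t, i, "row sum != 1", s)
      if (i %in% ABSORBING_STATES && abs(row[i] - 1) > tol) {
        add(t, i, "absorbing state not a unit self-loop", row[i])
      }
    }
  }
  violations <- if (length(viol)) {
    do.call(rbind, viol)
  } else {
    data.frame(day = integer(), state = integer(),
               issue = character(), value = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(list(valid = nrow(violations) == 0L, violations = violations,
                 horizon = horizon),
            class = "tm_validation")
}

# Stop unless M validates; shared guard for the simulation entry points.
assert_valid_matrices <- function(M) {
  v <- validate_matrices(M)
  if (!v$valid) {
    stop("transition matrices failed validation (",
         nrow(v$violations), " violating rows); see validate_matrices()",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read daily transition matrices from CSV
#'
#' The file schema is long format with columns `day` (1-based),
#' `from_state` (1--8), `to_state` (1--8) and `probability`.  Missing
#' `(from, to)` pairs are read as probability 0.
#'
#' @param path Path to the CSV file.
#' @param arm Study arm the file describes.
#' @param horizon Number of daily matrices expected (default 30; inferred
#'   upward if the file contains later days).
#' @param validate Passed on to [transition_matrices()].
#' @return A `transition_matrices` object.
#' @export
read_matrix_csv <- function(path, arm, horizon = 30L, validate = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "from_state", "to_state", "probability")
  if (!all(need %in% names(d))) {
    stop("matrix CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$from_state < 1 | d$from_state > N_STATES) ||
      any(d$to_state < 1 | d$to_state > N_STATES) || any(d$day < 1)) {
    stop("matrix CSV contains out-of-range day or state ids", call. = FALSE)
  }
  horizon <- max(horizon, d$day)
  P <- array(0, dim = c(N_STATES, N_STATES, horizon))
  P[cbind(d$from_state, d$to_state, d$day)] <- d$probability
  transition_matrices(P, arm = arm, validate = validate)
}

#' Write daily transition matrices to CSV
#'
#' Inverse of [read_matrix_csv()]; zero entries are omitted.
#'
#' @param M A `transition_matrices` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  stopifnot(inherits(M, "transition_matrices"))
  idx <- which(M$P != 0, arr.ind = TRUE)
  d <- data.frame(
    day = idx[, 3], from_state = idx[, 1], to_state = idx[, 2],
    probability = M$P[idx]
  )
  d <- d[order(d$day, d$from_state, d$to_state), ]
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.transition_matrices <- function(x, ...) {
  cat("Daily transition matrices (", x$arm, " arm): ",
      N_STATES, " states x ", x$horizon, " days\n", sep = "")
  cat("Day 1 matrix:\n")
  m <- round(x$P[, , 1], 4)
  dimnames(m) <- list(paste0("s", 1:8), paste0("s", 1:8))
  print(m)
  invisible(x)
}

#' @export
print.tm_validation <- function(x, ...) {
  if (x$valid) {
    cat("Transition matrices valid (", x$horizon, " days).\n", sep = "")
  } else {
    cat("Transition matrices INVALID; violating rows:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
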