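# Probabilistic (replicate-level Monte Carlo) and one-way (tornado)
# sensitivity analyses.

#' Probabilistic sensitivity analysis
#'
#' Runs `n_reps` paired Monte Carlo replicates of `n_patients` per arm.
#' Replicate `r` simulates the CHG arm with seed `seed + 2r - 1` and the
#' reference arm with `seed + 2r`, so the whole analysis is reproducible
#' from one base seed.  Per replicate it records the mean cost per
#' patient in each arm, the per-state ever-entry counts, mean ICU days,
#' mean days spent in each state (which lets any cost table be re-applied
#' to the same trajectories, see [psa_delta_cost()]), and the incremental
#' cost and effect.
#'
#' @param M_chg,M_ref Validated `transition_matrices` for the CHG and
#'   reference arms.
#' @param params A [cost_parameters()] object (also supplies the WTP).
#' @param n_reps Number of replicates (default 1,000; at least 2 to form
#'   confidence intervals).
#' @param n_patients Patients per replicate per arm (default 1,000).
#' @param seed Base RNG seed.
#' @return An object of class `psa_result`: `replicates` (a data.frame
#'   with one row per replicate: `delta_effect`, `delta_cost`,
#'   `cost_chg`, `cost_ref`, CRBSI counts, ICU days), percentile
#'   summaries (`summary`), per-arm per-state occupancy summaries
#'   (`occupancy`), `prob_more_effective`, per-replicate days-in-state
#'   arrays, and the mean-level `ce` endpoints (a `ce`-like list with
#'   ICER, iNMB, NNT at the replicate means).
#' @export
run_psa <- function(M_chg, M_ref, params = cost_parameters(),
                    n_reps = 1000L, n_patients = 1000L, seed = 1L) {
  stopifnot(inherits(params, "cost_parameters"))
  if (n_reps < 2L) stop("n_reps must be >= 2 to form CIs", call. = FALSE)
  if (seed + 2 * n_reps >= 2^31) {
    stop("seed too large: seed + 2 * n_reps must stay below 2^31",
         call. = FALSE)
  }
  assert_valid_matrices(M_chg)
  assert_valid_matrices(M_ref)
  costs_chg <- build_state_costs(params, "CHG")
  costs_ref <- build_state_costs(params, "nonCHG")
  cum_chg <- cumulative_rows(M_chg$P)
  cum_ref <- cumulative_rows(M_ref$P)
  horizon <- M_chg$horizon

  days_chg <- matrix(0, n_reps, N_STATES)
  days_ref <- matrix(0, n_reps, N_STATES)
  ever_chg <- matrix(0, n_reps, N_STATES)
  ever_ref <- matrix(0, n_reps, N_STATES)
  rep_stats <- matrix(0, n_reps, 8)
  colnames(rep_stats) <- c("cost_chg", "cost_ref", "crbsi_chg",
                           "crbsi_ref", "icu_chg", "icu_ref",
                           "delta_effect", "delta_cost")

  one_arm <- function(cum, costs, s) {
    traj <- with_seed(s, function()
      sim_trajectories(cum, as.integer(n_patients), horizon))
    summarize_trajectories(traj, unclass(costs), "CHG")
  }
  for (r in seq_len(n_reps)) {
    a <- one_arm(cum_chg, costs_chg, seed + 2 * r - 1)
    b <- one_arm(cum_ref, costs_ref, seed + 2 * r)
    days_chg[r, ] <- a$days_in_state
    days_ref[r, ] <- b$days_in_state
    ever_chg[r, ] <- a$ever_counts
    ever_ref[r, ] <- b$ever_counts
    rep_stats[r, ] <- c(
      a$mean_cost, b$mean_cost, a$n_crbsi, b$n_crbsi,
      a$icu_days, b$icu_days,
      (b$n_crbsi - a$n_crbsi) / n_patients,
      a$mean_cost - b$mean_cost
    )
  }
  replicates <- as.data.frame(rep_stats)

  pct <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    c(mean = mean(x), lower = q[1], upper = q[2])
  }
  summary_tab <- t(vapply(replicates, pct, numeric(3)))
  occupancy <- list(
    CHG = t(apply(1000 * ever_chg / n_patients, 2, pct)),
    nonCHG = t(apply(1000 * ever_ref / n_patients, 2, pct))
  )
  rownames(occupancy$CHG) <- rownames(occupancy$nonCHG) <-
    paste0("state", 1:8)

  de <- mean(replicates$delta_effect)
  dc <- mean(replicates$delta_cost)
  ce <- list(
    delta_effect = de, delta_cost = dc,
    icer = if (de != 0) dc / de else NA_real_,
    inmb = de * params$wtp - dc,
    nnt = if (de > 0) as.integer(round_half_up(1 / de)) else NA_integer_,
    wtp = params$wtp
  )

  structure(list(
    replicates = replicates,
    summary = summary_tab,
    occupancy = occupancy,
    prob_more_effective = mean(replicates$delta_effect > 0),
    days_in_state = list(CHG = days_chg, nonCHG = days_ref),
    ce = ce,
    params = params,
    n_reps = n_reps,
    n_patients = n_patients,
    seed = seed
  ), class = "psa_result")
}

#' Re-cost a PSA under different cost parameters
#'
#' Because cost parameters only weight trajectories, the stored
#' per-replicate mean days in each state reproduce every replicate's
#' mean cost exactly under any cost table, without re-simulating.  Used
#' by the one-way sensitivity analysis on fixed matrices.
#'
#' @param psa A `psa_result`.
#' @param params A [cost_parameters()] object, possibly with one
#'   parameter moved off base case.
#' @param params_ref Optional distinct parameters for the reference arm
#'   (defaults to `params`), for one-way analyses that vary a single
#'   arm's input.
#' @return A list: per-replicate `delta_cost` vector, its `mean`, and
#'   percentile `lower` / `upper` bounds.
#' @export
psa_delta_cost <- function(psa, params, params_ref = params) {
  stopifnot(inherits(psa, "psa_result"))
  c_chg <- unclass(build_state_costs(params, "CHG"))
  c_ref <- unclass(build_state_costs(params_ref, "nonCHG"))
  dc <- as.numeric(psa$days_in_state$CHG %*% c_chg -
                     psa$days_in_state$nonCHG %*% c_ref)
  q <- stats::quantile(dc, c(0.025, 0.975), names = FALSE)
  list(delta_cost = dc, mean = mean(dc), lower = q[1], upper = q[2])
}

# Default tested ranges for the one-way analysis: the extra-stay
# parameter spans 1-26 days; the remaining inputs +/- 50% of base.
default_tornado_ranges <- function(params) {
  list(
    extra_los_crbsi = c(1, 26),
    c_dressing_chg = params$c_dressing_chg * c(0.5, 1.5),
    dressings_per_day_chg = params$dressings_per_day * c(0.5, 1.5),
    dressings_per_day_nonchg = params$dressings_per_day * c(0.5, 1.5),
    c_icu_day = params$c_icu_day * c(0.5, 1.5)
  )
}

# Apply one tornado parameter to the per-arm cost parameter pair.
set_tornado_param <- function(params_chg, params_ref, name, value) {
  if (name == "dressings_per_day_chg") {
    params_chg <- modify_costs(params_chg, dressings_per_day = value)
  } else if (name == "dressings_per_day_nonchg") {
    params_ref <- modify_costs(params_ref, dressings_per_day = value)
  } else {
    args <- stats::setNames(list(value), name)
    params_chg <- do.call(modify_costs, c(list(params_chg), args))
    params_ref <- do.call(modify_costs, c(list(params_ref), args))
  }
  list(chg = params_chg, ref = params_ref)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the between-arm cost difference with one parameter at a
#' time moved to the low and high end of its tested range, all else at
#' base case.  The transition matrices are held fixed, so by default the
#' evaluation uses the exact analytic expected cost
#' ([expected_cost()]), isolating the parameter effect from Monte Carlo
#' noise; `method = "psa"` instead re-weights the replicates of a
#' supplied [run_psa()] result and reports the replicate-mean
#' difference.
#'
#' @param params Base-case [cost_parameters()].
#' @param M_chg,M_ref Per-arm `transition_matrices` (required for
#'   `method = "analytic"`).
#' @param ranges Named list of `c(low, high)` tested values; defaults to
#'   1--26 days for `extra_los_crbsi` and +/- 50% of base for the CHG
#'   dressing cost, each arm's dressings per day
#'   (`dressings_per_day_chg`, `dressings_per_day_nonchg`) and the ICU
#'   day cost.
#' @param method `"analytic"` (default) or `"psa"`.
#' @param psa A `psa_result`, required when `method = "psa"`.
#' @return An object of class `tornado_result`: a data.frame with one
#'   row per parameter (`parameter`, `low`, `high`, `delta_cost_low`,
#'   `delta_cost_high`, `spread`), sorted by decreasing spread, with the
#'   base-case `delta_cost` as an attribute.
#' @export
tornado <- function(params, M_chg = NULL, M_ref = NULL, ranges = NULL,
                    method = c("analytic", "psa"), psa = NULL) {
  stopifnot(inherits(params, "cost_parameters"))
  method <- match.arg(method)
  if (is.null(ranges)) ranges <- default_tornado_ranges(params)
  if (!length(ranges)) stop("empty tornado range list", call. = FALSE)

  if (method == "analytic") {
    stopifnot(inherits(M_chg, "transition_matrices"),
              inherits(M_ref, "transition_matrices"))
    d_chg <- expected_days_in_state(M_chg)
    d_ref <- expected_days_in_state(M_ref)
    eval_dc <- function(p_chg, p_ref) {
      sum(d_chg * unclass(build_state_costs(p_chg, "CHG"))) -
        sum(d_ref * unclass(build_state_costs(p_ref, "nonCHG")))
    }
  } else {
    if (!inherits(psa, "psa_result")) {
      stop("method = 'psa' needs a psa_result", call. = FALSE)
    }
    eval_dc <- function(p_chg, p_ref) {
      psa_delta_cost(psa, p_chg, p_ref)$mean
    }
  }

  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    stopifnot(length(rg) == 2L)
    at <- function(v) {
      p <- set_tornado_param(params, params, nm, v)
      eval_dc(p$chg, p$ref)
    }
    lo <- at(rg[1]); hi <- at(rg[2])
    data.frame(parameter = nm, low = rg[1], high = rg[2],
               delta_cost_low = lo, delta_cost_high = hi,
               spread = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_delta_cost") <- eval_dc(params, params)
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Write the tornado table to CSV
#'
#' @param x A `tornado_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write cost-effectiveness plane points to CSV
#'
#' One row per PSA replicate: incremental effect (CRBSIs avoided per
#' patient) and incremental cost (EUR per patient).
#'
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_plane_csv <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  utils::write.csv(
    data.frame(replicate = seq_len(psa$n_reps),
               delta_effect = psa$replicates$delta_effect,
               delta_cost = psa$replicates$delta_cost),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", x$n_reps,
      " replicates x ", x$n_patients, " patients/arm\n", sep = "")
  s <- x$summary
  fmt <- function(row, scale = 1, digits = 2) {
    sprintf("%0.*f [%0.*f; %0.*f]", digits, scale * row["mean"],
            digits, scale * row["lower"], digits, scale * row["upper"])
  }
  cat("  CRBSI avoided per 1,000 :",
      fmt(s["delta_effect", ], 1000, 2), "\n")
  cat("  delta cost (EUR)        :", fmt(s["delta_cost", ]), "\n")
  cat("  mean cost CHG (EUR)     :", fmt(s["cost_chg", ]), "\n")
  cat("  mean cost non-CHG (EUR) :", fmt(s["cost_ref", ]), "\n")
  cat(sprintf("  P(CHG more effective)   : %.3f\n", x$prob_more_effective))
  ce <- x$ce
  cat(sprintf("  ICER  : %s EUR per CRBSI avoided\n",
              ifelse(is.na(ce$icer), "undefined",
                     sprintf("%.0f", ce$icer))))
  cat(sprintf("  iNMB  : %+.2f EUR/patient (WTP %.0f)\n", ce$inmb, ce$wtp))
  cat("  NNT   :", ifelse(is.na(ce$nnt), "undefined", ce$nnt), "\n")
  invisible(x)
}

#' Plot the cost-effectiveness plane
#'
#' Incremental effect (x, CRBSIs avoided per 1,000 patients) against
#' incremental cost (y, EUR per patient), one point per replicate; the
#' filled square marks the replicate mean and the origin the reference
#' strategy.
#'
#' @param x A `psa_result`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.psa_result <- function(x, ...) {
  de <- 1000 * x$replicates$delta_effect
  dc <- x$replicates$delta_cost
  graphics::plot(de, dc, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "CRBSI avoided per 1,000 patients (CHG vs non-CHG)",
                 ylab = "Incremental cost (EUR per patient)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::points(mean(de), mean(dc), pch = 15, cex = 1.4)
  invisible(x)
}

#' @export
print.tornado_result <- function(x, ...) {
  cat("One-way sensitivity analysis (base-case delta cost ",
      sprintf("%+.2f", attr(x, "base_delta_cost")), " EUR):\n", sep = "")
  print(as.data.frame(lapply(as.data.frame(x), function(col)
    if (is.numeric(col)) round(col, 2) else col)), row.names = FALSE)
  invisible(x)
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the between-arm cost difference obtained at
#' each parameter's low and high tested value, widest at the top; the
#' dashed line marks the base-case difference.
#'
#' @param x A `tornado_result`.
#' @param ... Further arguments passed to [graphics::barplot()]
#'   (ignored beyond standard graphical parameters).
#' @return `x`, invisibly.
#' @export
plot.tornado_result <- function(x, ...) {
  d <- as.data.frame(x)[nrow(x):1, ]
  lo <- pmin(d$delta_cost_low, d$delta_cost_high)
  hi <- pmax(d$delta_cost_low, d$delta_cost_high)
  base <- attr(x, "base_delta_cost")
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "Delta cost, CHG vs non-CHG (EUR/patient)",
                 ylab = "", main = "Tornado diagram")
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi,
                 seq_len(nrow(d)) + 0.35, col = "grey70")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter,
                 las = 1, cex.axis = 0.8)
  invisible(x)
}
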