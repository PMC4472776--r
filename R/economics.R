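# Economic endpoints: incremental cost, effect, ICER, iNMB, NNT,
# CRBSI-attributable length of stay.

#' Compare the two dressing strategies
#'
#' Computes the incremental endpoints from two simulated cohorts of equal
#' size.  Effect is the per-patient probability of avoiding a CRBSI:
#' `delta_effect = P(CRBSI | reference) - P(CRBSI | CHG)`, where a CRBSI
#' patient is one ever entering state 3 or 4.  Then
#' `icer = delta_cost / delta_effect` (EUR per CRBSI avoided),
#' `inmb = delta_effect * wtp - delta_cost` (EUR per patient), and
#' `nnt = 1 / delta_effect` rounded to the nearest integer (defined for
#' `delta_effect > 0`).
#'
#' @param chg `cohort_result` for the CHG arm.
#' @param ref `cohort_result` for the reference (non-CHG) arm.
#' @param wtp Willingness to pay per CRBSI avoided (EUR); defaults to the
#'   base-case value in [cost_parameters()].
#' @return An object of class `ce_result` with the incremental endpoints,
#'   per-arm subgroup cost means (patients with / without CRBSI) and
#'   per-arm plus pooled CRBSI-attributable extra length of stay.
#' @export
compare_arms <- function(chg, ref, wtp = cost_parameters()$wtp) {
  stopifnot(inherits(chg, "cohort_result"), inherits(ref, "cohort_result"))
  if (chg$n_patients != ref$n_patients) {
    stop("both arms must simulate the same number of patients",
         call. = FALSE)
  }
  delta_cost <- chg$mean_cost - ref$mean_cost
  delta_effect <- ref$n_crbsi / ref$n_patients -
    chg$n_crbsi / chg$n_patients
  icer <- if (delta_effect != 0) delta_cost / delta_effect else NA_real_
  inmb <- delta_effect * wtp - delta_cost
  nnt <- if (delta_effect > 0) {
    as.integer(round_half_up(1 / delta_effect))
  } else {
    NA_integer_
  }
  subgroup <- function(res) {
    f <- res$per_patient$crbsi
    c(crbsi = if (any(f)) mean(res$per_patient$cost[f]) else NA_real_,
      no_crbsi = if (any(!f)) mean(res$per_patient$cost[!f]) else NA_real_)
  }
  el_chg <- extra_los(chg, warn = FALSE)
  el_ref <- extra_los(ref, warn = FALSE)
  structure(list(
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    icer = icer,
    icer_defined = delta_effect != 0,
    inmb = inmb,
    nnt = nnt,
    wtp = wtp,
    subgroup_cost = list(CHG = subgroup(chg), nonCHG = subgroup(ref)),
    extra_los = c(CHG = el_chg, nonCHG = el_ref,
                  pooled = pool_extra_los(el_chg, el_ref)),
    n_patients = chg$n_patients
  ), class = "ce_result")
}

#' CRBSI-attributable extra ICU length of stay
#'
#' Mean ICU days (days in states 1--6) among patients ever entering a
#' CRBSI state minus the mean among the remaining patients.  Undefined
#' (NA, with a warning) when the cohort has no CRBSI patients or no
#' CRBSI-free patients.
#'
#' @param result A `cohort_result`.
#' @param warn Warn when the estimate is undefined (default `TRUE`).
#' @return Extra length of stay in days, or `NA`.
#' @export
extra_los <- function(result, warn = TRUE) {
  stopifnot(inherits(result, "cohort_result"))
  f <- result$per_patient$crbsi
  if (!any(f) || all(f)) {
    if (warn) {
      warning("extra LOS undefined: cohort lacks a CRBSI or a CRBSI-free ",
              "subgroup", call. = FALSE)
    }
    return(NA_real_)
  }
  mean(result$per_patient$icu_days[f]) -
    mean(result$per_patient$icu_days[!f])
}

#' Pool per-arm extra length-of-stay estimates
#'
#' Base-case pooling rule: the arithmetic mean of the two arms'
#' estimates.
#'
#' @param chg,ref Per-arm extra LOS estimates (days).
#' @return Pooled extra LOS (days); `NA` inputs are dropped.
#' @export
pool_extra_los <- function(chg, ref) {
  mean(c(chg, ref), na.rm = TRUE)
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (CHG vs non-CHG), n =",
      x$n_patients, "patients per arm\n")
  cat(sprintf("  delta cost       : %+.2f EUR/patient\n", x$delta_cost))
  cat(sprintf("  delta effect     : %.4f CRBSI avoided/patient (%.1f per 1,000)\n",
              x$delta_effect, 1000 * x$delta_effect))
  if (x$icer_defined) {
    cat(sprintf("  ICER             : %.0f EUR per CRBSI avoided\n", x$icer))
  } else {
    cat("  ICER             : undefined (delta effect = 0)\n")
  }
  cat(sprintf("  iNMB (WTP %.0f)  : %+.2f EUR/patient\n", x$wtp, x$inmb))
  cat("  NNT              :", ifelse(is.na(x$nnt), "undefined", x$nnt), "\n")
  el <- x$extra_los
  cat(sprintf("  extra LOS (days) : CHG %.2f, non-CHG %.2f, pooled %.2f\n",
              el[["CHG"]], el[["nonCHG"]], el[["pooled"]]))
  invisible(x)
}

#' @export
summary.ce_result <- function(object, ...) {
  sg <- object$subgroup_cost
  cat("Subgroup mean cost per patient (EUR):\n")
  tab <- rbind(CHG = sg$CHG, nonCHG = sg$nonCHG)
  print(round(tab, 2))
  print(object)
  invisible(object)
}

#' Serialize a cost-effectiveness result to CSV
#'
#' One row per endpoint (`name`, `value`), suitable for downstream
#' tabulation.
#'
#' @param x A `ce_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_csv <- function(x, path) {
  stopifnot(inherits(x, "ce_result"))
  d <- data.frame(
    name = c("delta_cost", "delta_effect", "icer", "inmb", "nnt", "wtp",
             "cost_crbsi_chg", "cost_no_crbsi_chg",
             "cost_crbsi_nonchg", "cost_no_crbsi_nonchg",
             "extra_los_chg", "extra_los_nonchg", "extra_los_pooled"),
    value = c(x$delta_cost, x$delta_effect, x$icer, x$inmb, x$nnt, x$wtp,
              x$subgroup_cost$CHG[["crbsi"]],
              x$subgroup_cost$CHG[["no_crbsi"]],
              x$subgroup_cost$nonCHG[["crbsi"]],
              x$subgroup_cost$nonCHG[["no_crbsi"]],
              x$extra_los[["CHG"]], x$extra_los[["nonCHG"]],
              x$extra_los[["pooled"]])
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
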