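# Unit-cost parameters and per-state daily cost construction.

#' Base-case unit-cost parameters (EUR 2013)
#'
#' Bundles every monetary and resource-use input of the cost model.  The
#' defaults are the base case for a French ICU: cost per ICU day from a
#' multicentre micro-costing study, dressing unit costs, catheter-change
#' and dermatitis-management costs, the direct cost of treating one CRBSI
#' episode, the CRBSI-attributable extra ICU length of stay, and the
#' willingness to pay per CRBSI avoided (set to the mean cost of one
#' infected patient under the reference dressing).
#'
#' @param c_icu_day Cost per ICU day (EUR/day).
#' @param c_dressing_chg CHG dressing cost (EUR/dressing).
#' @param c_dressing_film Non-antimicrobial transparent film dressing cost
#'   (EUR/dressing).
#' @param c_dressing_gauze Gauze-and-tape dressing cost (EUR/dressing).
#' @param dressings_per_day Dressings applied per day (count/day).
#' @param c_ct_change Cost per catheter change, venous and arterial
#'   averaged 50:50 (EUR/event).
#' @param c_crbsi_direct Direct cost of treating one CRBSI episode
#'   (EUR/episode).
#' @param extra_los_crbsi CRBSI-attributable extra ICU length of stay
#'   (days).
#' @param c_derm_removal,c_derm_dressings,c_derm_insertion Components of
#'   one contact-dermatitis episode: catheter removal, four gauze-and-tape
#'   dressings, catheter re-insertion (EUR/event).
#' @param wtp Willingness to pay per CRBSI avoided (EUR).
#' @return An object of class `cost_parameters` (a named list).
#' @export
#' @examples
#' p <- cost_parameters()
#' build_state_costs(p, "CHG")
cost_parameters <- function(c_icu_day = 1265.93,
                            c_dressing_chg = 3.59,
                            c_dressing_film = 0.18,
                            c_dressing_gauze = 0.06,
                            dressings_per_day = 1,
                            c_ct_change = 94.97,
                            c_crbsi_direct = 580.26,
                            extra_los_crbsi = 9.33,
                            c_derm_removal = 23.62,
                            c_derm_dressings = 0.24,
                            c_derm_insertion = 94.87,
                            wtp = 41424) {
  p <- list(
    c_icu_day = c_icu_day, c_dressing_chg = c_dressing_chg,
    c_dressing_film = c_dressing_film, c_dressing_gauze = c_dressing_gauze,
    dressings_per_day = dressings_per_day, c_ct_change = c_ct_change,
    c_crbsi_direct = c_crbsi_direct, extra_los_crbsi = extra_los_crbsi,
    c_derm_removal = c_derm_removal, c_derm_dressings = c_derm_dressings,
    c_derm_insertion = c_derm_insertion, wtp = wtp
  )
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    stop("cost parameters must be single non-negative numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$dressings_per_day <= 0) {
    stop("dressings_per_day must be > 0", call. = FALSE)
  }
  structure(p, class = "cost_parameters")
}

# Update a cost_parameters object, re-validating.
modify_costs <- function(params, ...) {
  upd <- list(...)
  stopifnot(all(names(upd) %in% names(unclass(params))))
  p <- unclass(params)
  p[names(upd)] <- upd
  do.call(cost_parameters, p)
}

# Commercial half-up rounding (round() is round-half-even), with a guard
# against binary representation error just below a half-cent boundary.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  y <- x * p
  floor(y + 0.5 + abs(y) * 1e-12) / p
}

#' Cost of one complete CRBSI episode
#'
#' Direct treatment cost plus the attributable extra ICU stay valued at
#' the daily ICU cost.  The extra-stay component is held at cent
#' resolution, the working precision of all monetary inputs.
#'
#' @param params A [cost_parameters()] object.
#' @return Episode cost in EUR.
#' @export
crbsi_episode_cost <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  params$c_crbsi_direct +
    round_half_up(params$extra_los_crbsi * params$c_icu_day, 2)
}

#' Build per-state daily costs for one arm
#'
#' Every transient state (1--6) carries the ICU day cost plus the arm's
#' daily dressing cost; state 2 adds one catheter change; states 3 and 4
#' add the full CRBSI episode cost (direct treatment plus attributable
#' extra stay), charged on the single day the CRBSI state is occupied;
#' state 4 also adds a catheter change; state 5 adds the
#' dermatitis-management bundle; state 6 swaps the arm's dressing for
#' gauze and tape (identical in both arms).  The absorbing states cost
#' nothing.
#'
#' @param params A [cost_parameters()] object.
#' @param arm `"CHG"` or `"nonCHG"`; selects the dressing unit cost.
#' @return An object of class `state_costs`: a named numeric vector of
#'   length 8 (EUR per occupied day) with attributes `arm` and `params`.
#' @export
#' @examples
#' round(build_state_costs(cost_parameters(), "CHG"))
build_state_costs <- function(params, arm) {
  stopifnot(inherits(params, "cost_parameters"))
  arm <- match_arm(arm)
  dressing_day <- params$dressings_per_day *
    if (arm == "CHG") params$c_dressing_chg else params$c_dressing_film
  episode <- crbsi_episode_cost(params)
  derm <- params$c_derm_removal + params$c_derm_dressings +
    params$c_derm_insertion
  c1 <- params$c_icu_day + dressing_day
  costs <- c(
    c1,
    c1 + params$c_ct_change,
    c1 + episode,
    c1 + episode + params$c_ct_change,
    c1 + derm,
    params$c_icu_day + params$c_dressing_gauze,
    0,
    0
  )
  names(costs) <- paste0("state", 1:8)
  structure(costs, arm = arm, params = params, class = "state_costs")
}

#' @export
print.state_costs <- function(x, ...) {
  cat("Per-state daily costs (EUR), ", attr(x, "arm"), " arm:\n", sep = "")
  tab <- data.frame(
    state = 1:8, label = health_states()$label,
    cost = round_half_up(unclass(x), 2),
    rounded = round_half_up(unclass(x))
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
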