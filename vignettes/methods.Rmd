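---
title: "Methods: an eight-state daily Markov microsimulation for catheter-dressing cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an eight-state daily Markov microsimulation for catheter-dressing cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crbsicea)
```

## The decision problem and the model

`crbsicea` compares two strategies for securing central vascular lines
in ICU patients: an antimicrobial chlorhexidine gluconate (CHG)
securement dressing and non-antimicrobial transparent film dressings.
The clinical outcome is the catheter-related bloodstream infection
(CRBSI) avoided; the economic outcome is the incremental cost per
patient over a 30-day ICU horizon.

Each patient is an independent discrete-time Markov chain over eight
health states (see `health_states()`): four states crossing CRBSI
status with the need for a new catheter, contact dermatitis, a
gauze-and-tape fallback dressing, and two absorbing states (ICU
discharge, death).  The cycle length is one day and the chain is
*non-homogeneous*: a separate 8×8 row-stochastic matrix governs every
day, which is what lets the CRBSI hazard grow with catheterization
time.  Every patient starts day 1 in state 1; day `t`'s matrix governs
the move to day `t + 1`.

Key structural assumptions, mirrored throughout the code and tests:

* CRBSI states last exactly one day.  The full episode cost — direct
  treatment plus the attributable extra ICU stay valued at the daily
  ICU cost — is charged on the diagnosis day.  Clinically the episode
  continues, but its end is not observable in daily records, so the
  cost is front-loaded instead of spread.
* A dermatitis day always leads to the gauze-and-tape dressing, and the
  dermatitis-to-gauze transition probability is common to both arms.
* Once under gauze and tape, a patient follows the *reference* arm's
  transition dynamics: they no longer wear the study dressing, so the
  CHG arm's state-6 rows are copied from the non-CHG arm (estimation)
  or built from the reference hazards (generation).
* Discharge and death are absorbing and cost nothing; an ICU day is a
  day spent in states 1–6, and the absorption day itself is not an ICU
  day.

## Cost construction

`cost_parameters()` carries the base-case unit costs (EUR 2013): ICU
day €1,265.93; dressings €3.59 (CHG), €0.18 (film), €0.06 (gauze and
tape) at one dressing per day; catheter change €94.97;
dermatitis management €118.73 in three components; direct CRBSI
treatment €580.26; CRBSI-attributable extra stay 9.33 days (the mean of
the two arms' 8.55 and 10.1-day subgroup estimates); willingness to pay
€41,424 per CRBSI avoided (the mean cost of one infected reference-arm
patient).  `build_state_costs()` assembles per-state daily costs:
state 1 is an ICU day plus the arm's dressing; state 2 adds a catheter
change; states 3/4 add the CRBSI episode; state 5 adds the dermatitis
bundle; state 6 swaps in the gauze-and-tape dressing and is identical
in both arms.

Two numerical conventions matter.  Monetary amounts are handled at cent
resolution: the extra-stay episode component is rounded to the cent
inside `crbsi_episode_cost()`, which is also what makes the per-state
euro figures come out consistently when composed from printed
cent-level inputs.  Rounding for display uses commercial half-up
rounding (`round_half_up()`), not banker's rounding; all accounting
upstream of display is otherwise unrounded.  One base-case note: the
printed state costs are only consistent with exactly one dressing per
day, although observed ICU practice changes dressings less often; the
parameter is therefore exposed (`dressings_per_day`) and varied
per arm in the one-way analysis.

## Estimation from records

`estimate_matrices()` turns longitudinal patient-day records into daily
matrices by count ratios, `p_ij(t) = n_ij(t) / n_i(t)`.
`preprocess_records()` first censors beyond day 30, back-dates a CRBSI
recorded within two days after discharge to the discharge day (late
blood-culture confirmation), and enforces absorbing permanence.

Records are sparse late in the horizon, so some (state, day) rows have
no occupants.  The fallback chain — nearest earlier day with data, then
the time-pooled row for that state, then a self-loop — keeps every
matrix stochastic without inventing transitions the data contradict;
each fallback is logged in the result's `fallbacks` attribute.  This
fallback is a package design choice: daily clinical data admit several
defensible conventions here, and ours favours temporal locality.

## Simulation and its analytic oracle

`simulate_cohort()` draws trajectories by sequential categorical
sampling from each day's row — for an independent-patient chain with
known daily matrices this is the natural reading of chain-based
patient-level sampling, as there is no joint posterior to explore.
Sampling is vectorized over patients via cumulative row probabilities.
Reproducibility contract: an explicit seed yields a bit-identical
cohort; the caller's RNG stream is saved and restored.  In the
probabilistic sensitivity analysis, replicate `r` uses sub-seeds
`seed + 2r - 1` (CHG) and `seed + 2r` (reference), so one base seed
reproduces the entire analysis.

Every simulated quantity has a closed-form twin used as the test
oracle: `expected_occupancy()` (forward products
`pi(t+1) = pi(t) P(t)`), `expected_cost()`
(`sum_t sum_s pi_s(t) c_s`), and `expected_summaries()`, which also
computes the probability of *ever* entering a state by evolving the
never-entered mass and deleting the flow into the state each day
(taboo probabilities) — necessary because states 2–5 are recurrent, so
expected visits overcount patients.

## Economics

`compare_arms()` computes Δc (CHG minus reference mean cost), Δe
(reference minus CHG CRBSI risk, patients ever in states 3/4),
ICER = Δc/Δe, iNMB = Δe·WTP − Δc, and NNT = 1/Δe rounded to the nearest
integer (the half-up rule; the published integer is consistent with
either nearby risk difference).  With Δe = 0 the ICER is flagged
undefined while the iNMB remains computable.  `extra_los()` recovers
the CRBSI-attributable stay as the CRBSI / non-CRBSI contrast in mean
ICU days; the base case pools the two arms' estimates by their
arithmetic mean.

## Sensitivity analyses

The probabilistic analysis is replicate-level Monte Carlo (default
1,000 replicates × 1,000 patients per arm): no second-order parameter
distributions are imposed, matching the source design.  Confidence
intervals are percentile (2.5th/97.5th across replicates); the interval
type was an open choice and percentile intervals make no normality
assumption.

The tornado analysis varies one parameter at a time: the extra stay
over 1–26 days, and ±50% of base for the CHG dressing cost, each arm's
dressings per day, and the ICU day cost.  The ±50% ranges are package
defaults (overridable), not published tested ranges, so their spreads
are not comparable with published ones; the extra-stay range is the
published one.  Because all five parameters act only through the cost
table, the matrices stay fixed and the default evaluation uses the
exact analytic cost — Δc is then affine in the extra stay with slope
equal to the between-arm difference in expected CRBSI days times the
ICU day cost.  `method = "psa"` instead re-weights a stored PSA's
per-replicate days-in-state, which reproduces every replicate's cost
under the new parameters exactly without re-simulating.

## The synthetic generator and its calibration

The source trial's daily matrices are not public, so the package ships
synthetic ones with the same statistical structure.
`hazard_parameters()` encodes per-arm competing daily hazards:
piecewise-constant discharge and death hazards over three day bands
(1–5, 6–15, 16–30 — enough freedom to shape the absorption timing),
a linearly increasing CRBSI hazard `h0 + slope·t` (slope ≥ 0 encodes
rising infection risk with catheter dwell time), constant dermatitis
and new-catheter hazards, and the fraction of CRBSIs needing a new
catheter (state 4 vs 3), defaulting to the observed per-arm ratio —
all CRBSIs in state 4 for the CHG arm, 9.5:5.3 for the reference arm.
Dermatitis patients spend exactly one day in state 5 and then switch
dressings.

`calibrate_hazards()` fits nine log-scale parameters per arm by
Nelder–Mead on the *analytic* summaries (deterministic objective, no
simulation noise), minimizing squared relative errors against the
target profile: ever-entry counts for states 2, 3+4 and 5, the
discharge and death fractions, and mean ICU days.  The shipped
fixtures reach all six targets to relative errors below 1e-12.

The published profile also reports conditional mean days to discharge
(18.7/18.4) and death (25.2/25.3).  These are deliberately *not*
fitted, because the three summary groups are mutually infeasible for
any 30-day state model: mean ICU days is an accounting identity,
roughly `P(discharge)·(d7 − 1) + P(death)·(d8 − 1) + P(censored)·30`,
which evaluates to about 21 days at the reported absorption fractions
and conditional days — incompatible with the reported ≈12.9 ICU days
that the cost level (≈€16.5k at ≈€1.27k/day) independently confirms.
Fitting the absorption-day values would therefore corrupt the
quantities the cost model depends on; the reported values likely
summarize something other than the first-entry day.  The generator's
conditional absorption days come out near 12–15 instead.

## What the synthetic data do and do not show

The generator emulates: two arms with a five-fold CRBSI risk ratio,
rare infections with time-increasing hazard, realistic absorption and
ICU-day profiles, arm-specific dermatitis and catheter-change
frequencies, and the gauze-and-tape coupling between arms.  It does not
emulate patient covariates (age, sex, severity), catheter-level
structure, correlated within-patient event histories beyond the Markov
property, or any stay-prolonging effect of CRBSI beyond survival-time
selection.  Tests passing on synthetic data therefore validate the
machinery — estimation, simulation, costing, economics — under the
model's own assumptions; they cannot validate the clinical realism of
the source matrices themselves, which would require the trial data.

## Problem sizes and numerics

The test suite runs the full-scale analysis (1,000 × 1,000 per arm)
once, plus reduced designs (hundreds of replicates or patients)
everywhere a property does not need full scale; round-trip estimation
checks use 20,000–50,000 synthetic patients, where every frequent
transition cell is estimated from ≥50 occupants.  Stochastic
assertions use exact binomial tail bounds or 3-standard-error bounds
with explicit aggregation across simultaneous cells.  Row-stochasticity
is enforced to 1e-9; matrix CSVs store probabilities to 17 significant
digits so files round-trip within that tolerance.  Calibration is
deterministic given its seed (used only to jitter optimizer restarts).

## Known limitations

* The shipped matrices are calibrated emulations; per-cell agreement
  with the source trial's matrices is out of reach by design.
* The effect measure is CRBSIs avoided only — no QALYs, no survival
  weighting, no currency conversion beyond EUR 2013.
* One statistical unit: the patient; catheter-level data are out of
  scope.
* The empty-row fallback and the post-CRBSI return-to-state-1 routing
  are modelling conventions the daily-records format cannot pin down.
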