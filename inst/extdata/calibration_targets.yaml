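# Cohort-occupancy calibration targets, per 1,000 simulated patients.
# ever-entry counts for states 2-6, absorbing fractions (discharge,
# death), mean ICU days, and the conditional mean day of absorption.
# days_to_discharge / days_to_death are reported for reference but not
# fitted (see the methods vignette on target feasibility).
CHG:
  state2: 278.2
  state3: 0.0
  state4: 3.1
  state5: 28.8
  state6: 28.8
  discharge: 604.1
  death: 263.7
  icu_days: 12.91
  days_to_discharge: 18.74
  days_to_death: 25.17
nonCHG:
  state2: 251.6
  state3: 5.3
  state4: 9.5
  state5: 12.7
  state6: 12.7
  discharge: 613.4
  death: 270.7
  icu_days: 12.72
  days_to_discharge: 18.43
  days_to_death: 25.28
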