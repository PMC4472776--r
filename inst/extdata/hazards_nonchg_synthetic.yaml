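arm: nonCHG
h_discharge:
- 0.04987769342473546
- 0.04472450990017798
- 0.05379803799458781
h_death:
- 0.02112778854325569
- 0.02149476769464263
- 0.02202765619956402
crbsi_h0: 0.00058505674768133
crbsi_slope: 5.85056747681330955e-05
h_derm: 0.00101971365717603
h_newct: 0.02556694180670607
frac_newct: 0.64189189189189189
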