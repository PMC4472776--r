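arm: CHG
h_discharge:
- 0.05998942449306761
- 0.0370360027579841
- 0.04704177181552671
h_death:
- 0.0343091630582327
- 0.00330569265766732
- 0.02962441729661977
crbsi_h0: 0.00010379364147437
crbsi_slope: 1.03793641474370815e-05
h_derm: 0.00230874963267497
h_newct: 0.02967824403432927
frac_newct: 1.0
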