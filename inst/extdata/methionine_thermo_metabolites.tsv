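metabolite	x_min	x_max
Met	0.00166667	1.5
AdoMet	0.002	1.8
AdoHcy	1e-04	0.09
Hcy	3.33333e-05	0.03
MTHF	6.66667e-05	0.06
CH2THF	3.33333e-05	0.03
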