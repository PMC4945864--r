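reaction	dG0
MATI	-40.4702
MATIII	-40.4702
GNMT	-22.2749
METH	-4.2749
AHC	-5.167
BHMT	-20.0879
MS	-12.3005
MTHFR	-23.7874
CBS	-20.813
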