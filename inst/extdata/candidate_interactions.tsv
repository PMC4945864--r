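enzyme	effector	sign
MATIII	AdoMet	activation
GNMT	AdoHcy	inhibition
GNMT	MTHF	inhibition
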