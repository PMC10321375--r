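pam_pattern	penalty
NGG	1
NAG	0.26
NCG	0.11
NTG	0.02
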