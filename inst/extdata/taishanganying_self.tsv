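class	count
Pps-S1+Pps-S2	0
Pps-S1+Pps-S4	41
Pps-S1+Pps-S6	9
Pps-S2+Pps-S4	0
Pps-S2+Pps-S6	0
Pps-S4+Pps-S6	0
Pps-S1+Pps-S2+Pps-S4	124
Pps-S1+Pps-S2+Pps-S6	13
Pps-S1+Pps-S4+Pps-S6	133
Pps-S2+Pps-S4+Pps-S6	3
Pps-S1+Pps-S2+Pps-S4+Pps-S6	127
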