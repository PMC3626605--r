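class	count
Pps-S1+Pps-S2	0
Pps-S1+Pps-S5	90
Pps-S1+Pps-S8	4
Pps-S2+Pps-S5	0
Pps-S2+Pps-S8	0
Pps-S5+Pps-S8	53
Pps-S1+Pps-S2+Pps-S5	14
Pps-S1+Pps-S2+Pps-S8	6
Pps-S1+Pps-S5+Pps-S8	211
Pps-S2+Pps-S5+Pps-S8	0
Pps-S1+Pps-S2+Pps-S5+Pps-S8	60
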