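class	count
Pa-S1+Pps-S1+Pps-S2	2
Pa-S1+Pps-S1+Pps-S4	5
Pa-S1+Pps-S1+Pps-S6	5
Pa-S1+Pps-S2+Pps-S4	0
Pa-S1+Pps-S2+Pps-S6	0
Pa-S1+Pps-S4+Pps-S6	2
Pa-S2+Pps-S1+Pps-S2	4
Pa-S2+Pps-S1+Pps-S4	1
Pa-S2+Pps-S1+Pps-S6	1
Pa-S2+Pps-S2+Pps-S4	0
Pa-S2+Pps-S2+Pps-S6	1
Pa-S2+Pps-S4+Pps-S6	3
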