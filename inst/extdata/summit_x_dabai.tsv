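class	count
Pa-S1+Pps-S1+Pps-S2	2
Pa-S1+Pps-S1+Pps-S5	8
Pa-S1+Pps-S1+Pps-S8	10
Pa-S1+Pps-S2+Pps-S5	0
Pa-S1+Pps-S2+Pps-S8	0
Pa-S1+Pps-S5+Pps-S8	5
Pa-S2+Pps-S1+Pps-S2	4
Pa-S2+Pps-S1+Pps-S5	5
Pa-S2+Pps-S1+Pps-S8	5
Pa-S2+Pps-S2+Pps-S5	0
Pa-S2+Pps-S2+Pps-S8	0
Pa-S2+Pps-S5+Pps-S8	10
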