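# Batch-culture growth of B. braunii 779 in BB medium: cell dry weight
# (g/L), three replicate cultures, sampled every two days.
day	rep1	rep2	rep3
0	0.140	0.155	0.155
2	0.215	0.245	0.235
4	0.600	0.640	0.630
6	0.920	0.960	0.970
8	1.150	1.350	1.300
10	1.500	1.700	1.650
12	1.900	2.200	1.900
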