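# Batch-culture growth of B. braunii 779 in 2x BB medium (doubled
# nutrient strength): cell dry weight (g/L), three replicate cultures.
day	rep1	rep2	rep3
0	0.140	0.155	0.155
2	0.730	0.755	0.750
4	1.610	1.580	1.630
6	2.250	2.500	2.550
8	3.000	3.000	3.300
10	3.500	3.850	3.850
12	3.800	4.300	4.050
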