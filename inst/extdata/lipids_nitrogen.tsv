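# Gravimetric lipid measurements of log-phase B. braunii 779 cultures
# before (N_replete) and three days after (N_depleted) transfer to
# nitrogen-free medium. CDW = cell dry weight, TL = total lipid,
# HC = hydrocarbon; rep1-3 individual measurements, average as reported.
condition	component	rep1	rep2	rep3	average
N_replete	CDW	1.61	1.58	1.63	1.61
N_replete	TL	0.59	0.60	0.56	0.58
N_replete	HC	0.30	0.36	0.28	0.31
N_depleted	CDW	1.67	1.67	1.70	1.68
N_depleted	TL	1.25	1.29	1.23	1.25
N_depleted	HC	0.87	0.84	0.92	0.87
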