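conf_threshold	tp	tn	fp	fn
0.25	24	6	9	2
0.30	23	8	6	3
0.35	17	10	3	9
0.40	9	12	1	17
0.45	5	12	0	21
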