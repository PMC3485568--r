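subject	paradigm	rvcbv_pct	q_act_pct	dy_act
1	A	36.8	-36.9	0.148
2	A	23.6	-56.1	0.224
3	A	33.3	-33.6	0.134
4	A	33.7	-39.9	0.160
5	A	18.7	-36.9	0.148
6	A	32.1	-31.0	0.124
7	A	30.7	-35.2	0.141
8	B	44.6	-43.4	0.174
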