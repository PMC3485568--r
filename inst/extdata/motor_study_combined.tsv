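subject	paradigm	rcbf_pct	dy_act	q_act_assumed_pct	rcmro2_assumed_pct	q0_measured	q_act_measured_pct	rcmro2_measured_pct
5	A	58.0	0.116	-29.0	12.2	0.424	-27.4	14.8
6	A	57.8	0.119	-29.8	10.9	0.487	-24.4	19.3
7	A	87.2	0.103	-25.8	39.0	0.381	-27.0	36.7
8	B	87.4	0.164	-40.9	10.7	0.346	-47.3	-1.1
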