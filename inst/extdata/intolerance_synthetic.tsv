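gene	esp6500_pct	exac_pct	local_pct	pli	mis_z
EPYC	38.5	41.2	36	0.01	-0.40000000000000002
SPOCK1	62	58.299999999999997	60.5	0.35999999999999999	1.1000000000000001
MYBPC1	55.100000000000001	49.700000000000003	52	0.02	0.29999999999999999
ACSS3	44	46.5	.	0.08	0.20000000000000001
NRP1	71.200000000000003	74.799999999999997	69	0.88	1.8
POT1	84.5	88.099999999999994	86.200000000000003	0.92000000000000004	2.1000000000000001
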