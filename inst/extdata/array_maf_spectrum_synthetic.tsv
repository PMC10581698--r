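lower	upper	mass
0.00	0.05	0.04
0.05	0.10	0.06
0.10	0.15	0.08
0.15	0.20	0.09
0.20	0.25	0.10
0.25	0.30	0.11
0.30	0.35	0.12
0.35	0.40	0.13
0.40	0.45	0.13
0.45	0.50	0.14
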