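# synthetic RBS position weight matrix, consensus tvaGGag
# (constructed for testing and as a placeholder; not literature-derived)
# threshold 2.54
# ramp 0.4
A	C	G	T
0.05	0.05	0.05	0.25
0.15	0.15	0.15	0.02
0.30	0.05	0.05	0.05
0.00	0.00	0.80	0.00
0.00	0.00	0.80	0.00
0.35	0.05	0.15	0.05
0.15	0.05	0.30	0.05
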