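primer_base	A	C	G	T	gap	N
A	0	1.0	1.2	1.0	1.5	1.0
C	1.2	0	1.6	1.2	1.5	1.0
G	0.6	1.2	0	1.0	1.5	1.0
T	1.0	0.6	1.2	0	1.5	1.0
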