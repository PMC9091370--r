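id	formula	lb	ub
R1	-> A	5	5
R2	-> C	0	20
R3	A <-> 2 B	-500	1000
R4	B + C ->	0	1000
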