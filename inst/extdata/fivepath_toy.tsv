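id	equation	lb	ub	category	gene_associated
EX_A	A ->	-10	0	exchange	0
R1	A -> B	0	20	internal	1
R2	B -> C	0	20	internal	1
R3	A -> C	0	20	internal	1
R4	A -> E	0	20	internal	1
R5	B -> F	0	20	internal	1
EX_E	E ->	0	20	exchange	0
EX_F	F ->	0	20	exchange	0
GROWTH	C ->	0	20	biomass	0
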