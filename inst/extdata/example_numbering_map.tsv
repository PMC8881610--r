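chain	auth_seq	res_name	generic_label	region
R	138	GLN	1.40b	TM1
R	183	ARG	2.60b	TM2
R	190	ARG	2.67b	TM2
R	202	GLY		ECL1
R	224	GLN	3.37b	TM3
R	227	VAL	3.40b	TM3
R	300	ARG	5.40b	TM5
R	344	LYS	6.35b	TM6
P	7	THR	7P	
P	27	LEU	27P	
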