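name	direction	sequence	gene	product_len_bp	annealing_tm_c	source
C1-J-2495	F	CAGCTACTTTATGAGCTTTAGG	COXI	278	48	literature
C1-N-2800	R	CATTTCAAGCTGTGTAAGCATC	COXI	278	48	literature
COX2-519	F	TGGAACCCCTGGACGACTTA	COXII	97	53	newly_designed
COX2-615	R	ACTGTGATTAGCTCCGCAAA	COXII	97	53	newly_designed
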