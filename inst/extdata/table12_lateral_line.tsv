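species	N	71	72	73	74	75	76	77	78	79	80	81	82	83	84	85	86	87	88	89	90	91	92	93
C.litoralis_contemporary	13											1	2			1	3	1			1		1	3
C.gutturosus	10						1	2	3	1	2		1
C.macrophthalmus	7			1			1		1	1	3
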