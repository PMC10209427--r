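species	N	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37	38	39	40
C.litoralis_contemporary	13				1		3	2	1	1	3	1	1
C.intermundia	10										2			1	2	3		2
C.nobilis_contemporary	21														2		2	4	8	3	2
C.obliterus	7	1	1	1	1	2	1
C.sarnensis	28													1	4	7	7	5	3		1
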