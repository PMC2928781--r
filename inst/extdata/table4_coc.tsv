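strain	chromosome	interval1	interval2	dco_obs	dco_exp_printed	coc_printed	p_printed	interference
wild-type	III	HIS4-LEU2	LEU2-CEN3	5	17.5	0.286	0.004	YES
msh4-R676W	III	HIS4-LEU2	LEU2-CEN3	14	16.2	0.864	0.667	NO
wild-type	III	LEU2-CEN3	CEN3-MAT	16	19.7	0.813	0.465	NO
msh4-R676W	III	LEU2-CEN3	CEN3-MAT	31	24.8	1.251	0.242	NO
wild-type	VII	TRP5-CYH2	CYH2-MET13	57	64.4	0.886	0.363	NO
msh4-R676W	VII	TRP5-CYH2	CYH2-MET13	27	38.7	0.698	0.064	NO
wild-type	VII	CYH2-MET13	MET13-LYS5	20	38.9	0.514	0.002	YES
msh4-R676W	VII	CYH2-MET13	MET13-LYS5	12	22.9	0.523	0.027	YES
wild-type	VIII	CEN8-THR1	THR1-CUP1	67	107.2	0.625	<0.0001	YES
msh4-R676W	VIII	CEN8-THR1	THR1-CUP1	43	71	0.606	0.0005	YES
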