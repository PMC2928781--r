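strain	chromosome	interval	npd_obs	npd_exp_printed	ratio_printed	p_printed	interference
wild-type	VII	TRP5-CYH2	9	33.4	0.269	<0.0001	YES
msh4-R676W	VII	TRP5-CYH2	3	17.0	0.176	0.0001	YES
wild-type	VIII	CEN8-THR1	2	12.5	0.16	0.0007	YES
msh4-R676W	VIII	CEN8-THR1	2	8.15	0.245	0.0186	YES
wild-type	VIII	THR1-CUP1	1	17.56	0.056	<0.0001	YES
msh4-R676W	VIII	THR1-CUP1	5	11.63	0.430	0.030	YES
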