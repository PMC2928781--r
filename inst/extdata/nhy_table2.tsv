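strain	chromosome	interval	spores_n	parental	recombinant	cM_spore	ci_low	ci_high	PD	TT	NPD	cM_tetrad	se_tetrad
wild-type	III	HIS4-LEU2	2711	2360	351	12.9	11.7	14.3	413	141	2	13.8	1.2
msh4-R676W	III	HIS4-LEU2	3041	2763	278	9.1	8.2	10.2	562	116	1	9.0	0.8
msh4-E276A	III	HIS4-LEU2	933	841	92	9.9	8.1	11.9	165	42	0	10.1	1.4
msh5-S416A	III	HIS4-LEU2	939	870	69	7.3	5.8	9.2	174	26	0	6.5	1.2
msh5-D539A	III	HIS4-LEU2	942	875	67	7.1	5.6	8.9	182	29	0	6.9	1.2
msh5-D532A	III	HIS4-LEU2	1089	1016	73	6.7	5.4	8.3	192	24	1	6.9	1.7
msh4d	III	HIS4-LEU2	760	716	44	5.8	4.3	7.7	93	11	0	5.3	1.5
msh5d	III	HIS4-LEU2	739	708	31	4.2	3.0	5.9	102	8	0	3.6	1.2
wild-type	III	LEU2-CEN3	2711	2527	184	6.8	5.9	7.8	488	68	0	6.1	0.7
msh4-R676W	III	LEU2-CEN3	3041	2816	225	7.4	6.5	8.4	585	93	1	7.3	0.8
msh4-E276A	III	LEU2-CEN3	933	876	57	6.1	4.7	7.8	182	25	0	6.0	1.1
msh5-S416A	III	LEU2-CEN3	939	854	85	9.1	7.4	11.1	170	30	0	7.5	1.3
msh5-D539A	III	LEU2-CEN3	942	880	62	6.6	5.2	8.3	183	28	0	6.6	1.2
msh5-D532A	III	LEU2-CEN3	1089	1009	80	7.3	6.0	9.0	198	19	0	4.4	1.0
msh4d	III	LEU2-CEN3	760	678	82	10.8	8.8	13.2	96	8	0	3.8	1.3
msh5d	III	LEU2-CEN3	739	685	54	7.3	5.6	9.4	104	6	0	2.7	1.1
wild-type	III	CEN3-MAT	2711	2309	402	14.8	13.5	16.2	395	160	1	14.9	1.0
msh4-R676W	III	CEN3-MAT	3041	2629	412	13.5	12.4	14.8	500	175	4	14.7	1.2
msh4-E276A	III	CEN3-MAT	933	803	130	13.9	11.9	16.3	151	54	2	15.9	2.5
msh5-S416A	III	CEN3-MAT	939	835	104	11.1	9.2	13.2	155	45	0	11.3	1.5
msh5-D539A	III	CEN3-MAT	942	807	135	14.3	12.2	16.7	154	57	0	13.5	1.5
msh5-D532A	III	CEN3-MAT	1089	1001	88	8.1	6.6	9.8	182	35	0	8.1	1.3
msh4d	III	CEN3-MAT	760	719	41	5.4	4.0	7.2	97	7	0	3.4	1.2
msh5d	III	CEN3-MAT	739	716	23	3.1	2.0	4.6	104	6	0	2.7	1.1
wild-type	VII	TRP5-CYH2	2711	1803	908	33.5	31.7	35.2	197	337	9	36.0	1.8
msh4-R676W	VII	TRP5-CYH2	3041	2379	662	21.8	20.3	23.2	378	282	3	22.6	1.2
msh4-E276A	VII	TRP5-CYH2	933	743	190	20.4	17.9	23.1	125	77	2	21.8	2.6
msh5-S416A	VII	TRP5-CYH2	939	729	210	22.4	19.8	25.1	108	84	3	26.2	3.0
msh5-D539A	VII	TRP5-CYH2	942	736	206	21.9	19.3	24.6	115	88	1	23.0	2.2
msh5-D532A	VII	TRP5-CYH2	1089	881	208	19.1	16.9	21.5	136	73	1	18.8	2.1
msh4d	VII	TRP5-CYH2	760	622	138	18.2	15.6	21.1	66	30	1	18.6	3.7
msh5d	VII	TRP5-CYH2	739	620	119	16.1	13.6	18.9	68	28	0	14.6	2.3
wild-type	VII	CYH2-MET13	2711	2451	260	9.6	8.5	10.8	442	101	0	9.3	0.8
msh4-R676W	VII	CYH2-MET13	3041	2806	235	7.7	6.8	8.7	573	89	1	7.2	0.8
msh4-E276A	VII	CYH2-MET13	933	873	60	6.4	5.0	8.2	178	26	0	6.4	1.2
msh5-S416A	VII	CYH2-MET13	939	884	55	5.9	4.5	7.5	175	20	0	5.1	1.0
msh5-D539A	VII	CYH2-MET13	942	861	81	8.6	7.0	10.6	171	33	0	8.1	1.3
msh5-D532A	VII	CYH2-MET13	1089	1035	54	5.0	3.8	6.4	191	19	0	4.5	1.0
msh4d	VII	CYH2-MET13	760	715	45	5.9	4.4	7.8	89	8	0	4.1	1.4
msh5d	VII	CYH2-MET13	739	695	44	6.0	4.5	7.9	94	1	1	3.6	3.1
wild-type	VII	MET13-LYS5	2711	2152	559	20.6	19.1	22.2	334	205	4	21.1	1.5
msh4-R676W	VII	MET13-LYS5	3041	2627	414	13.6	12.4	14.9	494	168	1	13.1	1.0
msh4-E276A	VII	MET13-LYS5	933	818	115	12.3	10.4	14.6	155	49	0	12.0	1.5
msh5-S416A	VII	MET13-LYS5	939	815	124	13.2	11.2	15.5	147	48	0	12.3	1.5
msh5-D539A	VII	MET13-LYS5	942	806	136	14.4	12.3	16.8	152	52	0	12.7	1.5
msh5-D532A	VII	MET13-LYS5	1089	981	108	9.9	8.3	11.8	179	30	1	8.6	1.8
msh4d	VII	MET13-LYS5	760	656	104	13.7	11.4	16.3	76	20	1	13.4	3.6
msh5d	VII	MET13-LYS5	739	630	109	14.7	12.4	17.5	76	19	1	13.0	3.6
wild-type	VIII	CEN8-THR1	2711	2105	606	22.4	20.8	24.0	317	219	2	21.5	1.3
msh4-R676W	VIII	CEN8-THR1	3041	2557	484	15.9	14.7	17.3	467	199	2	15.8	1.1
msh4-E276A	VIII	CEN8-THR1	933	813	120	12.9	10.9	15.1	153	46	0	11.6	1.5
msh5-S416A	VIII	CEN8-THR1	939	799	140	14.9	12.8	17.3	147	54	0	13.4	1.6
msh5-D539A	VIII	CEN8-THR1	942	828	114	12.1	10.2	14.3	155	44	0	11.1	1.5
msh5-D532A	VIII	CEN8-THR1	1089	973	116	10.7	9.0	12.6	180	29	1	8.3	1.8
msh4d	VIII	CEN8-THR1	760	665	95	12.5	10.3	15.0	82	15	0	7.7	1.8
msh5d	VIII	CEN8-THR1	739	654	85	11.5	9.4	14.0	92	9	0	4.5	1.4
wild-type	VIII	THR1-CUP1	2711	2043	668	24.6	23.0	26.3	277	260	1	24.7	1.2
msh4-R676W	VIII	THR1-CUP1	3041	2475	566	18.6	17.3	20.0	432	231	5	19.5	1.3
msh4-E276A	VIII	THR1-CUP1	933	766	167	17.9	15.6	20.5	130	69	0	17.3	1.7
msh5-S416A	VIII	THR1-CUP1	939	777	162	17.3	15.0	19.8	133	68	0	16.9	1.7
msh5-D539A	VIII	THR1-CUP1	942	764	178	18.9	16.5	21.5	127	72	0	18.1	1.7
msh5-D532A	VIII	THR1-CUP1	1089	967	122	11.2	9.5	13.2	173	36	1	10.0	1.9
msh4d	VIII	THR1-CUP1	760	651	109	14.3	12.0	17.0	74	23	0	11.9	2.2
msh5d	VIII	THR1-CUP1	739	647	92	12.4	10.3	15.0	83	17	1	11.4	3.4
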