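drug1	drug2	enzymes	risk1	risk2	risk12	rr	p_value	m1	n1	m2	n2	m12	n12
loratadine	simvastatin	CYP3A4/5	0.022	0.033	0.093	1.69	2.03e-07	1264	44245	4197	102345	137	1223
loratadine	alprazolam	CYP3A4/5	0.022	0.029	0.095	1.86	2.44e-08	1257	43341	2251	52341	176	1448
loratadine	duloxetine	CYP2D6	0.020	0.047	0.130	1.94	5.60e-07	1220	43552	1385	23470	90	631
loratadine	ropinirole	CYP2D6	0.020	0.018	0.122	3.21	2.60e-07	1218	43491	164	6531	17	123
promethazine	tegaserod	CYP2D6	0.011	0.020	0.093	3.00	8.22e-07	1332	78334	109	3745	23	224
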