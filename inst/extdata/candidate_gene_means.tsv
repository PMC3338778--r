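gene	category	wt_mean	wt_sd	het_mean	het_sd	mut_mean	mut_sd	printed_fold	footnote
Acta1	actin	1449	107	1544	349	2486	230	1.8	two_array
Enah	actin	133	8	152	1	194	111	1.5	adhesome
Actg2	actin	96	23	113	14	129	27	1.3	adhesome
Palld	actin	294	21	352	23	376	113	1.3	two_array
Actn3	actin	1123	256	1017	88	650	17	-1.7	adhesome
Csrp1	actin	819	174	820	52	526	94	-1.6	two_array
Ptpn11	actin	119	7	106	16	87	16	-1.4	none
Tpm3	actin	192	43	196	18	155	29	-1.2	none
Cap1	actin	1253	274	1257	293	1031	338	-1.2	none
Mapt	microtubule	44	3	51	13	256	144	5.8	two_array
Stmn2	microtubule	32	14	26	2	131	32	4.0	two_array
Stmn3	microtubule	71	2	62	21	236	106	3.3	two_array
Shroom3	microtubule	396	54	438	39	501	61	1.3	none
Tubb4	microtubule	130	56	141	84	165	29	1.3	adhesome
Tubb3	microtubule	170	61	113	11	216	93	1.3	two_array
Tubb2b	microtubule	2216	312	2504	198	2766	426	1.2	two_array
Tubb5	microtubule	2079	91	1670	66	1460	45	-1.4	two_array
Dctn4	microtubule	129	13	122	31	94	45	-1.4	none
Myoz2	adhesion	189	11	211	35	319	69	1.7	two_array
Itga4	adhesion	1985	261	2180	427	2920	663	1.5	two_array
Adamts9	adhesion	169	92	167	32	239	63	1.4	two_array
Cyr61	adhesion	521	22	542	6	732	183	1.4	two_array
Fbln2	adhesion	372	167	357	23	467	16	1.4	two_array
Smoc1	adhesion	261	27	282	40	347	40	1.3	none
Spnb2	adhesion	123	1	147	11	162	67	1.3	two_array
Fat3	adhesion	441	55	466	8	578	72	1.3	two_array
Rnf165	adhesion	124	20	152	42	160	16	1.3	adhesome
Sdc4	adhesion	188	15	200	5	127	29	-1.5	two_array
Sdc2	adhesion	360	42	404	61	251	37	-1.4	two_array
Adam19	adhesion	250	24	222	14	192	0	-1.3	adhesome
Ctgf	adhesion	158	44	198	87	104	22	-1.3	two_array
Sgpp1	adhesion	169	43	145	6	128	33	-1.3	none
Jam3	adhesion	1258	137	1197	55	959	38	-1.3	two_array
Lmo7	adhesion	180	96	158	56	141	57	-1.3	none
Postn	adhesion	2110	186	1722	28	1625	77	-1.3	two_array
Tspan33	adhesion	367	133	375	30	300	23	-1.2	adhesome
Prkar2b	signaling	118	9	137	58	185	15	1.6	two_array
Pdpk1	signaling	632	127	356	34	293	114	-2.2	two_array
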