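cluster_id	n_arrays	n_ge5	pct_ge5	total_bp	pct_genome	n_monomers	mean_monomers_per_array	gc_pct	consensus_length
CL1	1397	507	36.29	1067806	0.19	6432	4.6	39.22	167
CL2	1031	453	43.94	855355	0.15	5183	5.05	36.85	166
CL3	703	234	33	531465	0.1	3209	4.56	31.16	167
CL4	684	167	24.4	460902	0.08	2754	4.03	36.51	170
CL5	643	62	9.64	359046	0.06	2005	3.12	31.6	181
CL6	598	123	20.5	346142	0.06	2384	3.99	39.57	147
CL7	564	42	7.44	345312	0.06	1957	3.47	41.24	178
CL8	488	47	9.63	263021	0.05	1635	3.35	32.96	162
CL9	307	25	8.14	182211	0.03	1059	3.45	33.2	173
CL10	227	64	28.19	153409	0.03	927	4.08	34.66	167
CL11	213	0	0	82801	0.01	509	2.39	30.91	162
CL12	156	1	0.64	47771	0.01	356	2.28	44.92	138
CL13	140	4	2.86	62802	0.01	380	2.72	32.29	168
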