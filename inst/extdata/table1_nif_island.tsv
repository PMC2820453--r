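locus_id	gene_name	shock_ratio	nfix_fold	nifa_flag	rpon_flag
PST1302	.	0.06	16.83	.	.
PST1303	.	0.03	53.99	.	.
PST1304	nifQ	0.03	46.56	.	.
PST1305	.	0.03	38.67	.	.
PST1306	nifB	0.06	21.46	Yes	Yes
PST1307	.	0.57	1.87	No	Yes
PST1308	.	0.43	2.22	No	No
PST1309	.	0.84	1.12	No	No
PST1310	.	1.03	1.02	No	No
PST1311	.	0.81	1.34	No	Yes
PST1312	tpmA	0.34	2.65	No	Yes
PST1313	nifA	0.15	6.95	.	.
PST1314	nifL	0.12	7.68	Yes	Yes
PST1315	rnfA	0.37	2.66	Yes	Yes
PST1316	rnfB	0.10	9.94	.	.
PST1317	rnfC	0.49	2.22	.	.
PST1318	rnfD	0.13	7.67	.	.
PST1319	rnfG	0.16	7.47	.	.
PST1320	rnfE	0.15	8.80	.	.
PST1321	rnfH	0.21	17.55	.	.
PST1322	nifY2	0.10	21.74	.	.
PST1323	.	0.18	13.73	.	.
PST1324	.	0.15	25.99	.	.
PST1325	.	0.15	9.68	Yes	Yes
PST1326	nifH	0.32	94.05	Yes	Yes
PST1327	nifD	0.56	54.16	.	.
PST1328	nifK	0.62	38.22	.	.
PST1329	nifT	1.70	7.82	.	.
PST1330	nifY	0.33	8.51	.	.
PST1331	.	0.41	12.55	.	.
PST1332	.	0.57	3.27	No	Yes
PST1333	nifE	0.05	35.82	Yes	Yes
PST1334	nifN	0.07	13.32	.	.
PST1335	nifX	0.10	37.97	.	.
PST1336	.	0.29	5.06	.	.
PST1337	.	0.05	63.84	.	.
PST1338	.	0.08	31.07	Yes	Yes
PST1339	.	0.76	2.94	.	.
PST1340	.	0.82	1.28	.	.
PST1341	.	0.85	1.28	.	.
PST1342	.	0.43	3.69	.	.
PST1343	.	0.70	2.56	.	.
PST1344	.	0.21	7.16	Yes	Yes
PST1345	modC	0.79	1.59	.	.
PST1346	modB	0.48	2.05	.	.
PST1347	modA	0.20	4.12	.	.
PST1348	.	0.22	3.88	Yes	Yes
PST1349	hesB	0.07	20.92	Yes	Yes
PST1350	nifU	0.11	10.77	.	.
PST1351	nifS	0.11	16.21	.	.
PST1352	nifV	0.05	24.55	.	.
PST1353	cysE	0.05	32.98	.	.
PST1354	.	0.10	11.11	.	.
PST1355	nifW	0.16	26.04	.	.
PST1356	nifZ	0.17	18.17	.	.
PST1357	nifM	0.19	18.78	.	.
PST1358	.	0.56	8.42	.	.
PST1359	nifF	0.86	14.91	Yes	Yes
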