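index	label	basc_index	x	y	z	network_group	is_global_signal
0	ParOcc assoc	100	7.13	-76.26	25.61	NA	FALSE
1	Amy	71	3.06	-7.47	-19.9	NA	FALSE
2	pIns	21	-2.01	-7.26	-3.49	NA	FALSE
3	SensMot	8	-40.99	-22.62	61.9	NA	FALSE
4	Angular	50	-29.83	-72.86	31.94	NA	FALSE
5	r aPFC	92	42.57	42.79	10.85	NA	FALSE
6	Cer V	48	-0.4	-46.11	-23.17	NA	FALSE
7	pCing	19	-1.47	-63.33	8.28	NA	FALSE
8	Cer VII	18	1.9	-79.54	-48.01	NA	FALSE
9	Coll s	79	-4.4	-41.99	-12.66	NA	FALSE
10	iParietal	114	-48.23	-65.34	33.46	NA	FALSE
11	Marg s	118	-0.23	-30.3	47.49	NA	FALSE
12	aIns	85	10.94	22.89	4.96	NA	FALSE
13	Vis assoc	43	12.89	-83.54	18.77	NA	FALSE
14	aPFC	87	1.64	62.77	13.2	NA	FALSE
15	STG	88	0.66	-5.24	-0.93	NA	FALSE
16	Put	25	-2.8	-2.14	4.11	NA	FALSE
17	Vis assoc 2	16	2.23	-95.23	14.76	NA	FALSE
18	dPCC	72	-1.71	-49.05	7.1	NA	FALSE
19	sParietal	76	0.57	-25.77	3.98	NA	FALSE
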