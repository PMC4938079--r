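# pulsewave segment table
id	name	length_cm	r_mm	cff_ms	cqa_ms	parent	terminal
1	aorta I	1.94	12.4 -> 13.2	4.56 -> 4.56	4.56 -> 4.42		FALSE
2	aorta II	2.06	13.2 -> 13.2	4.56 -> 4.56	4.42 -> 4.42	1	FALSE
3	aorta III	2	13.2 -> 12.8	4.56 -> 4.56	4.42 -> 4.49	2	FALSE
4	aorta IV	0.58	12.8 -> 12.3	4.56 -> 4.56	4.49 -> 4.56	3	FALSE
5	aorta V	0.57	12.3 -> 11.8	4.56 -> 4.56	4.56 -> 4.66	4	FALSE
6	aorta VI	0.85	11.8 -> 11.1	4.56 -> 4.56	4.66 -> 4.81	5	FALSE
7	aorta VII	0.48	11.1 -> 10.9	4.56 -> 4.56	4.81 -> 4.86	6	FALSE
8	aorta VIII	1.52	10.9 -> 10.7	4.56 -> 4.56	4.86 -> 4.91	7	FALSE
9	aorta IX	2.06	10.7 -> 10.6	4.56 -> 4.56	4.91 -> 4.93	8	FALSE
10	aorta X	1.94	10.6 -> 10	4.56 -> 4.56	4.93 -> 5.08	9	FALSE
11	aorta XI	2	10 -> 9.3	4.56 -> 4.56	5.08 -> 5.27	10	FALSE
12	aorta XII	1.97	9.3 -> 9.1	4.56 -> 4.56	5.27 -> 5.31	11	FALSE
13	aorta XIII	2.03	9.1 -> 8.8	4.56 -> 4.56	5.31 -> 5.41	12	FALSE
14	aorta XIV	2	8.8 -> 8.6	4.56 -> 4.56	5.41 -> 5.46	13	FALSE
15	aorta XV	2	8.6 -> 8.5	4.56 -> 4.56	5.46 -> 5.5	14	FALSE
16	aorta XVI	1.1	8.5 -> 8.3	4.56 -> 4.56	5.5 -> 5.57	15	FALSE
17	aorta XVII	2.9	8.3 -> 7.8	4.56 -> 4.56	5.57 -> 5.76	16	FALSE
18	aorta XVIII	2.41	7.8 -> 7.5	4.56 -> 4.56	5.76 -> 5.87	17	FALSE
19	aorta XIX	1.59	7.5 -> 7.5	4.56 -> 4.56	5.87 -> 5.85	18	FALSE
20	aorta XX	1.56	7.5 -> 7.5	4.56 -> 4.56	5.85 -> 5.84	19	TRUE
21	brachiocephalic I	2	7 -> 4.5	4.56 -> 4.56	6.06 -> 7.54	4	FALSE
22	brachiocephalic II	2.2	4.5 -> 4.3	4.56 -> 4.56	7.54 -> 7.77	21	TRUE
23	left carotid I	2	5.1 -> 3.1	4.56 -> 4.56	7.1 -> 9.18	5	FALSE
24	left carotid II	1.23	3.1 -> 2.9	4.56 -> 4.56	9.18 -> 9.43	23	TRUE
25	left subclavian I	2	5.3 -> 3.5	4.56 -> 4.56	6.97 -> 8.64	6	FALSE
26	left subclavian II	1.31	3.5 -> 3.4	4.56 -> 4.56	8.64 -> 8.67	25	TRUE
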