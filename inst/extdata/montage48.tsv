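channel	source	detector	roi
1	1	1	rSTC
2	2	2	rSTC
3	3	3	rSTC
4	4	4	rSTC
5	5	5	rVLPFC
6	6	6	rVLPFC
7	7	7	rVLPFC
8	8	8	rVLPFC
9	9	9	rVLPFC
10	10	10	rDLPFC
11	11	11	rDLPFC
12	12	12	rDLPFC
13	13	13	rDLPFC
14	14	14	rDLPFC
15	15	15	rDLPFC
16	1	16	mPFC
17	2	1	mPFC
18	3	2	lDLPFC
19	4	3	lDLPFC
20	5	4	lDLPFC
21	6	5	lDLPFC
22	7	6	lDLPFC
23	8	7	lDLPFC
24	9	8	mPFC
25	10	9	mPFC
26	11	10	rSFC
27	12	11	rSFC
28	13	12	rSFC
29	14	13	rSFC
30	15	14	rSFC
31	1	15	lSFC
32	2	16	mPFC
33	3	1	mPFC
34	4	2	lSFC
35	5	3	mPFC
36	6	4	mPFC
37	7	5	lSFC
38	8	6	lSFC
39	9	7	lSFC
40	10	8	lVLPFC
41	11	9	lVLPFC
42	12	10	lVLPFC
43	13	11	lVLPFC
44	14	12	lVLPFC
45	15	13	lSTC
46	1	14	lSTC
47	2	15	lSTC
48	3	16	lSTC
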