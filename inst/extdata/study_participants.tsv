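participant	gender	age	perceived_performance	bci_experience
1	F	27	0.85	Yes
3	M	29	0.95	Yes
4	M	60	0.35	No
5	M	27	NA	No
6	M	22	0.7	Yes
7	F	23	0.75	Yes
8	M	24	0.2	Yes
9	M	24	0.75	Yes
10	F	23	0.8	Yes
11	F	22	0.075	Yes
12	F	33	0.6	No
13	F	24	0.5	No
14	M	22	0.15	Yes
15	M	24	0.35	No
16	M	21	0.6	No
17	M	28	0.35	No
18	M	26	0.45	Yes
19	F	25	0.5	Yes
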