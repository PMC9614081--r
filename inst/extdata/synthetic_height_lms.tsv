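sex	age_years	L	M	S
male	6	1	119.38	0.042
male	6.5	1	119.99	0.042
male	7	1	120.74	0.042
male	7.5	1	121.66	0.042
male	8	1	122.78	0.042
male	8.5	1	124.13	0.042
male	9	1	125.74	0.042
male	9.5	1	127.63	0.042
male	10	1	129.82	0.042
male	10.5	1	132.31	0.042
male	11	1	135.08	0.042
male	11.5	1	138.07	0.042
male	12	1	141.24	0.042
male	12.5	1	144.5	0.042
male	13	1	147.76	0.042
male	13.5	1	150.93	0.042
male	14	1	153.92	0.042
male	14.5	1	156.69	0.042
male	15	1	159.18	0.042
male	15.5	1	161.37	0.042
male	16	1	163.26	0.042
male	16.5	1	164.87	0.042
male	17	1	166.22	0.042
male	17.5	1	167.34	0.042
male	18	1	168.26	0.042
female	6	1	119.02	0.04
female	6.5	1	119.85	0.04
female	7	1	120.89	0.04
female	7.5	1	122.16	0.04
female	8	1	123.69	0.04
female	8.5	1	125.52	0.04
female	9	1	127.64	0.04
female	9.5	1	130.05	0.04
female	10	1	132.71	0.04
female	10.5	1	135.56	0.04
female	11	1	138.5	0.04
female	11.5	1	141.44	0.04
female	12	1	144.29	0.04
female	12.5	1	146.95	0.04
female	13	1	149.36	0.04
female	13.5	1	151.48	0.04
female	14	1	153.31	0.04
female	14.5	1	154.84	0.04
female	15	1	156.11	0.04
female	15.5	1	157.15	0.04
female	16	1	157.98	0.04
female	16.5	1	158.64	0.04
female	17	1	159.16	0.04
female	17.5	1	159.58	0.04
female	18	1	159.9	0.04
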