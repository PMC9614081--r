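sex	age_years	L	M	S
male	6	-1.6	15.72	0.125
male	6.5	-1.58	15.8	0.124
male	7	-1.56	15.9	0.123
male	7.5	-1.54	16.01	0.122
male	8	-1.52	16.14	0.121
male	8.5	-1.5	16.29	0.12
male	9	-1.48	16.47	0.119
male	9.5	-1.46	16.66	0.118
male	10	-1.44	16.88	0.117
male	10.5	-1.42	17.13	0.116
male	11	-1.4	17.39	0.115
male	11.5	-1.38	17.67	0.114
male	12	-1.36	17.97	0.113
male	12.5	-1.34	18.28	0.112
male	13	-1.32	18.6	0.111
male	13.5	-1.3	18.92	0.11
male	14	-1.28	19.23	0.109
male	14.5	-1.26	19.53	0.108
male	15	-1.24	19.81	0.107
male	15.5	-1.22	20.07	0.106
male	16	-1.2	20.32	0.105
male	16.5	-1.18	20.54	0.104
male	17	-1.16	20.73	0.103
male	17.5	-1.14	20.91	0.102
male	18	-1.12	21.06	0.101
female	6	-1.4	15.51	0.115
female	6.5	-1.3825	15.59	0.1143
female	7	-1.365	15.69	0.1135
female	7.5	-1.3475	15.82	0.1128
female	8	-1.33	15.96	0.112
female	8.5	-1.3125	16.12	0.1113
female	9	-1.295	16.31	0.1105
female	9.5	-1.2775	16.52	0.1098
female	10	-1.26	16.76	0.109
female	10.5	-1.2425	17.02	0.1082
female	11	-1.225	17.31	0.1075
female	11.5	-1.2075	17.6	0.1068
female	12	-1.19	17.91	0.106
female	12.5	-1.1725	18.22	0.1053
female	13	-1.155	18.53	0.1045
female	13.5	-1.1375	18.83	0.1038
female	14	-1.12	19.12	0.103
female	14.5	-1.1025	19.39	0.1023
female	15	-1.085	19.63	0.1015
female	15.5	-1.0675	19.85	0.1008
female	16	-1.05	20.04	0.1
female	16.5	-1.0325	20.21	0.0993
female	17	-1.015	20.36	0.0985
female	17.5	-0.9975	20.48	0.0978
female	18	-0.98	20.59	0.097
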