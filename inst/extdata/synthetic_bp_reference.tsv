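sex	age_years	height_band	sbp_p90	sbp_p95	dbp_p90	dbp_p95
female	6	<P5	114.4	118.2	69.4	72.1
female	6	P5-P25	115.5	119.3	69.8	72.6
female	6	P25-P50	116.6	120.4	70.3	73
female	6	P50-P75	117.7	121.5	70.7	73.5
female	6	P75-P95	118.8	122.6	71.2	73.9
female	6	>=P95	119.9	123.7	71.6	74.4
female	7	<P5	115.9	119.7	70	72.8
female	7	P5-P25	117	120.8	70.5	73.2
female	7	P25-P50	118.1	121.9	70.9	73.7
female	7	P50-P75	119.2	123	71.4	74.1
female	7	P75-P95	120.3	124.1	71.8	74.6
female	7	>=P95	121.4	125.2	72.3	75
female	8	<P5	117.3	121.1	70.7	73.4
female	8	P5-P25	118.4	122.2	71.1	73.9
female	8	P25-P50	119.5	123.3	71.6	74.3
female	8	P50-P75	120.6	124.4	72	74.8
female	8	P75-P95	121.7	125.5	72.5	75.2
female	8	>=P95	122.8	126.6	72.9	75.7
female	9	<P5	118.8	122.6	71.3	74.1
female	9	P5-P25	119.9	123.7	71.8	74.5
female	9	P25-P50	121	124.8	72.2	75
female	9	P50-P75	122.1	125.9	72.7	75.4
female	9	P75-P95	123.2	127	73.1	75.9
female	9	>=P95	124.3	128.1	73.6	76.3
female	10	<P5	120.2	124	72	74.7
female	10	P5-P25	121.3	125.1	72.4	75.2
female	10	P25-P50	122.4	126.2	72.9	75.6
female	10	P50-P75	123.5	127.3	73.3	76.1
female	10	P75-P95	124.6	128.4	73.8	76.5
female	10	>=P95	125.7	129.5	74.2	77
female	11	<P5	121.7	125.5	72.6	75.4
female	11	P5-P25	122.8	126.6	73.1	75.8
female	11	P25-P50	123.9	127.7	73.5	76.3
female	11	P50-P75	125	128.8	74	76.7
female	11	P75-P95	126.1	129.9	74.4	77.2
female	11	>=P95	127.2	131	74.9	77.6
female	12	<P5	123.1	126.9	73.3	76
female	12	P5-P25	124.2	128	73.7	76.5
female	12	P25-P50	125.3	129.1	74.2	76.9
female	12	P50-P75	126.4	130.2	74.6	77.4
female	12	P75-P95	127.5	131.3	75.1	77.8
female	12	>=P95	128.6	132.4	75.5	78.3
female	13	<P5	124.6	128.4	73.9	76.7
female	13	P5-P25	125.7	129.5	74.4	77.1
female	13	P25-P50	126.8	130.6	74.8	77.6
female	13	P50-P75	127.9	131.7	75.3	78
female	13	P75-P95	129	132.8	75.7	78.5
female	13	>=P95	130.1	133.9	76.2	78.9
female	14	<P5	126	129.8	74.6	77.3
female	14	P5-P25	127.1	130.9	75	77.8
female	14	P25-P50	128.2	132	75.5	78.2
female	14	P50-P75	129.3	133.1	75.9	78.7
female	14	P75-P95	130.4	134.2	76.4	79.1
female	14	>=P95	131.5	135.3	76.8	79.6
female	15	<P5	127.5	131.3	75.2	78
female	15	P5-P25	128.6	132.4	75.7	78.4
female	15	P25-P50	129.7	133.5	76.1	78.9
female	15	P50-P75	130.8	134.6	76.6	79.3
female	15	P75-P95	131.9	135.7	77	79.8
female	15	>=P95	133	136.8	77.5	80.2
female	16	<P5	128.9	132.7	75.9	78.6
female	16	P5-P25	130	133.8	76.3	79.1
female	16	P25-P50	131.1	134.9	76.8	79.5
female	16	P50-P75	132.2	136	77.2	80
female	16	P75-P95	133.3	137.1	77.7	80.4
female	16	>=P95	134.4	138.2	78.1	80.9
female	17	<P5	130.4	134.2	76.5	79.3
female	17	P5-P25	131.5	135.3	77	79.7
female	17	P25-P50	132.6	136.4	77.4	80.2
female	17	P50-P75	133.7	137.5	77.9	80.6
female	17	P75-P95	134.8	138.6	78.3	81.1
female	17	>=P95	135.9	139.7	78.8	81.5
female	18	<P5	131.8	135.6	77.2	79.9
female	18	P5-P25	132.9	136.7	77.6	80.4
female	18	P25-P50	134	137.8	78.1	80.8
female	18	P50-P75	135.1	138.9	78.5	81.3
female	18	P75-P95	136.2	140	79	81.7
female	18	>=P95	137.3	141.1	79.4	82.2
male	6	<P5	115.9	119.7	69.9	72.6
male	6	P5-P25	117	120.8	70.3	73.1
male	6	P25-P50	118.1	121.9	70.8	73.5
male	6	P50-P75	119.2	123	71.2	74
male	6	P75-P95	120.3	124.1	71.7	74.4
male	6	>=P95	121.4	125.2	72.1	74.9
male	7	<P5	117.4	121.2	70.5	73.3
male	7	P5-P25	118.5	122.3	71	73.7
male	7	P25-P50	119.6	123.4	71.4	74.2
male	7	P50-P75	120.7	124.5	71.9	74.6
male	7	P75-P95	121.8	125.6	72.3	75.1
male	7	>=P95	122.9	126.7	72.8	75.5
male	8	<P5	118.8	122.6	71.2	73.9
male	8	P5-P25	119.9	123.7	71.6	74.4
male	8	P25-P50	121	124.8	72.1	74.8
male	8	P50-P75	122.1	125.9	72.5	75.3
male	8	P75-P95	123.2	127	73	75.7
male	8	>=P95	124.3	128.1	73.4	76.2
male	9	<P5	120.3	124.1	71.8	74.6
male	9	P5-P25	121.4	125.2	72.3	75
male	9	P25-P50	122.5	126.3	72.7	75.5
male	9	P50-P75	123.6	127.4	73.2	75.9
male	9	P75-P95	124.7	128.5	73.6	76.4
male	9	>=P95	125.8	129.6	74.1	76.8
male	10	<P5	121.7	125.5	72.5	75.2
male	10	P5-P25	122.8	126.6	72.9	75.7
male	10	P25-P50	123.9	127.7	73.4	76.1
male	10	P50-P75	125	128.8	73.8	76.6
male	10	P75-P95	126.1	129.9	74.3	77
male	10	>=P95	127.2	131	74.7	77.5
male	11	<P5	123.2	127	73.1	75.9
male	11	P5-P25	124.3	128.1	73.6	76.3
male	11	P25-P50	125.4	129.2	74	76.8
male	11	P50-P75	126.5	130.3	74.5	77.2
male	11	P75-P95	127.6	131.4	74.9	77.7
male	11	>=P95	128.7	132.5	75.4	78.1
male	12	<P5	124.6	128.4	73.8	76.5
male	12	P5-P25	125.7	129.5	74.2	77
male	12	P25-P50	126.8	130.6	74.7	77.4
male	12	P50-P75	127.9	131.7	75.1	77.9
male	12	P75-P95	129	132.8	75.6	78.3
male	12	>=P95	130.1	133.9	76	78.8
male	13	<P5	126.1	129.9	74.4	77.2
male	13	P5-P25	127.2	131	74.9	77.6
male	13	P25-P50	128.3	132.1	75.3	78.1
male	13	P50-P75	129.4	133.2	75.8	78.5
male	13	P75-P95	130.5	134.3	76.2	79
male	13	>=P95	131.6	135.4	76.7	79.4
male	14	<P5	127.5	131.3	75.1	77.8
male	14	P5-P25	128.6	132.4	75.5	78.3
male	14	P25-P50	129.7	133.5	76	78.7
male	14	P50-P75	130.8	134.6	76.4	79.2
male	14	P75-P95	131.9	135.7	76.9	79.6
male	14	>=P95	133	136.8	77.3	80.1
male	15	<P5	129	132.8	75.7	78.5
male	15	P5-P25	130.1	133.9	76.2	78.9
male	15	P25-P50	131.2	135	76.6	79.4
male	15	P50-P75	132.3	136.1	77.1	79.8
male	15	P75-P95	133.4	137.2	77.5	80.3
male	15	>=P95	134.5	138.3	78	80.7
male	16	<P5	130.4	134.2	76.4	79.1
male	16	P5-P25	131.5	135.3	76.8	79.6
male	16	P25-P50	132.6	136.4	77.3	80
male	16	P50-P75	133.7	137.5	77.7	80.5
male	16	P75-P95	134.8	138.6	78.2	80.9
male	16	>=P95	135.9	139.7	78.6	81.4
male	17	<P5	131.9	135.7	77	79.8
male	17	P5-P25	133	136.8	77.5	80.2
male	17	P25-P50	134.1	137.9	77.9	80.7
male	17	P50-P75	135.2	139	78.4	81.1
male	17	P75-P95	136.3	140.1	78.8	81.6
male	17	>=P95	137.4	141.2	79.3	82
male	18	<P5	133.3	137.1	77.7	80.4
male	18	P5-P25	134.4	138.2	78.1	80.9
male	18	P25-P50	135.5	139.3	78.6	81.3
male	18	P50-P75	136.6	140.4	79	81.8
male	18	P75-P95	137.7	141.5	79.5	82.2
male	18	>=P95	138.8	142.6	79.9	82.7
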