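region	t1_true_mean	t1_true_sd	t1_dl_mean	t1_dl_sd	t2_true_mean	t2_true_sd	t2_dl_mean	t2_dl_sd
Precentral	1219.05	188.74	1179.95	157.26	53.57	18.95	52.06	6.01
Frontal	1091.95	324.63	1034.93	263.09	56.47	25.18	55.25	21.38
Rolandic operculum	1157.36	337.79	1087.97	242.20	56.98	48.13	52.55	23.03
Superior motor area	1174.16	247.40	1137.35	236.75	54.84	42.99	59.62	55.05
Olfactory	1129.85	230.67	1101.78	208.78	52.75	24.97	53.41	13.02
Frontal superior medial	1240.88	174.22	1117.40	181.21	57.17	11.41	56.41	9.52
Frontal medial orbital	792.91	64.11	802.86	67.88	43.58	5.92	44.97	5.43
Rectus	1226.21	348.29	1211.80	311.57	56.93	21.15	59.02	17.90
Insula	1165.76	296.00	1110.20	235.98	48.41	18.41	47.56	8.36
Cingulum	1112.00	376.06	1041.23	264.94	58.04	49.78	53.23	22.49
Hippocampus	915.58	84.70	897.35	48.87	33.42	6.04	34.26	2.21
Amygdala	1225.21	248.49	1173.07	198.07	54.70	23.71	53.82	7.24
Calcarine	1158.93	371.97	1104.69	318.70	80.25	74.91	74.68	54.98
Cuneus	1229.30	175.10	1161.40	221.10	71.47	16.24	70.73	17.15
Lingual	810.18	53.54	835.18	98.76	52.95	7.96	54.00	7.51
Occipital	1234.78	344.30	1164.70	276.76	72.91	39.83	72.21	25.97
Fusiform	1316.22	466.33	1287.05	420.25	114.33	130.23	99.89	82.17
Postcentral	1196.08	248.40	1131.24	212.94	52.20	19.75	52.50	15.07
Parietal	1226.17	375.31	1198.44	347.56	55.63	31.66	53.94	16.21
Supramarginal gyrus	1251.48	237.10	1220.97	176.74	54.35	39.23	53.88	11.69
Angular	1338.31	320.69	1260.07	268.09	61.54	28.85	58.94	14.76
Precuneus	1182.13	330.25	1116.01	280.77	53.70	44.31	49.44	20.05
Paracentral lobule	997.40	286.32	944.59	215.99	51.52	23.10	50.74	15.05
Caudate	1240.88	174.22	1117.40	181.21	57.17	11.41	56.41	9.52
Putamen	792.91	64.11	802.86	67.88	43.58	5.92	44.97	5.43
Pallidum	1300.74	253.88	1223.73	197.90	49.93	12.68	51.44	7.02
Thalamus	923.59	89.64	871.30	59.08	33.14	6.12	35.20	2.73
Heschl's gyrus	1239.57	434.63	1210.43	390.69	81.42	77.59	69.18	46.19
Temporal	1221.05	265.70	1120.69	221.14	47.17	17.75	46.21	9.04
Cerebellum	1240.66	460.13	1188.84	406.53	88.44	106.28	80.91	82.54
Vermis	1225.46	161.34	1188.85	288.09	63.29	26.21	67.66	35.23
Pons	822.00	55.10	860.70	106.77	47.36	9.55	49.60	8.62
Dorsal mesopontine	943.77	189.18	897.25	145.36	37.06	11.99	36.64	5.60
Entorhinal cortex	1236.87	493.50	1181.11	429.46	101.21	130.68	84.23	88.25
Para hippocampal	1171.20	445.67	1133.52	397.63	94.37	118.86	85.84	98.44
Cingulum posterior	1243.10	385.92	1166.64	314.87	64.51	59.76	59.39	37.00
Retrosplenial cortex	1067.28	135.68	1011.14	114.93	43.35	8.84	43.92	4.73
Frontal gray matter	1171.88	280.44	1103.91	253.17	59.50	23.20	59.50	13.21
Occipital gray matter	1163.95	298.03	1079.83	221.73	44.45	17.36	44.00	7.75
Parietal gray matter	1294.66	399.55	1184.95	335.35	68.82	53.80	61.55	27.98
Temporal gray matter	1288.92	464.01	1272.09	430.48	97.22	104.14	89.89	87.38
Cerebellum gray matter	1165.18	383.41	1104.97	326.07	63.64	40.17	60.18	31.17
Frontal white matter	1123.70	303.51	1076.94	263.71	58.80	28.40	57.65	17.88
Occipital white matter	1239.66	178.45	1165.70	197.19	61.94	15.95	61.23	11.72
Parietal white matter	817.22	60.55	831.06	86.89	44.08	7.71	45.84	6.91
Temporal white matter	1043.98	195.88	1006.65	180.79	39.94	18.30	39.44	14.05
Cerebellum white matter	1287.52	321.54	1270.22	317.31	59.32	52.13	58.62	32.41
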