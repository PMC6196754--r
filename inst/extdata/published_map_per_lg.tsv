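lg	n_snps	phys_mb	female_cm	male_cm	sexavg_cm
LG01	2112	38.37	71.64	53.35	62.11
LG02	1749	35.26	68.22	80.97	66.27
LG03	1349	68.55	99.59	68.38	84.91
LG04	1707	38.04	60.9	62.85	61.39
LG05	1925	34.63	70.2	53.59	61.02
LG06	1948	44.57	71.66	80.09	73.6
LG07	3391	62.06	132.69	67.45	96.68
LG08	1607	30.80	84.18	72.48	77.72
LG09	1564	27.52	65.26	58.34	60.39
LG10	1387	32.43	63.42	56.51	59.69
LG11	1821	36.47	78.49	62.87	70.07
LG12	1979	41.23	69.03	56.09	61.99
LG13	1614	32.34	72.9	54.64	62.79
LG14	2030	39.26	69.67	55.02	61.99
LG15	1836	36.15	65	54.95	58.68
LG16	1862	43.86	71.61	59.94	64.36
LG17	2005	40.92	68.88	60.36	63.97
LG18	1628	37.01	63.14	61.85	62.1
LG19	1646	31.25	64.21	50.37	56.04
LG20	1899	36.77	81.26	62.64	71.31
LG22	1643	37.01	67.09	72.69	69.25
LG23	1484	44.10	73.86	54.17	63.36
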