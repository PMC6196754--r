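name	length_bp	variants	assigned
LG01	31194787	2571	TRUE
LG02	25048291	2043	TRUE
LG03	19325363	1415	TRUE
LG04	28679955	2288	TRUE
LG05	37389089	2927	TRUE
LG06	36725243	2891	TRUE
LG07	51042256	4128	TRUE
LG08	29447820	2314	TRUE
LG09	20956653	1732	TRUE
LG10	17092887	1414	TRUE
LG11	33447472	2653	TRUE
LG12	34679706	2753	TRUE
LG13	32787261	2647	TRUE
LG14	34191023	2700	TRUE
LG15	26684556	2180	TRUE
LG16	34890008	2777	TRUE
LG17	31749960	2609	TRUE
LG18	26198306	2075	TRUE
LG19	27159252	2223	TRUE
LG20	31470686	2491	TRUE
LG22	26410405	2083	TRUE
LG23	20779993	1603	TRUE
unmapped_scaffolds	246010115	5939	FALSE
mitochondrial_genome	16627	10	FALSE
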