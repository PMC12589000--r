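region	coverage	average_hit	pc90
Central Africa	63.33	1.32	0.27
Central America	15.29	0.22	0.12
East Africa	70.10	1.49	0.33
East Asia	63.42	1.32	0.27
Europe	89.13	2.94	0.92
North Africa	69.31	1.66	0.33
North America	84.69	2.43	0.65
Northeast Asia	52.38	0.91	0.21
Oceania	60.96	1.04	0.26
South Africa	55.74	1.32	0.23
South America	52.23	1.02	0.21
South Asia	71.86	1.8	0.36
Southeast Asia	54.27	0.86	0.22
Southwest Asia	55.18	1.18	0.22
West Africa	67.90	1.54	0.31
West Indies	77.19	1.99	0.44
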