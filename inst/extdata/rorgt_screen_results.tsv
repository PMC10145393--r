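compound	specs_id	ic50_um	ic50_estimate	status	mmgbsa_kcal	max_tanimoto
control	Ursolic acid	0.2	FALSE	control	NA	NA
1	AE-641/30156032	NA	FALSE	nb	-102.79	NA
2	AF-399/15599217	NA	FALSE	ns	-98.34	NA
3	AF-399/41318865	NA	FALSE	nb	-115.72	NA
4	AF-399/41895766	NA	FALSE	nb	-102.31	NA
5	AF-399/42017292	NA	FALSE	nb	-103.83	NA
6	AF-399/42017398	NA	FALSE	nb	-98.77	NA
7	AF-399/42017933	NA	FALSE	nb	-107.31	NA
8	AG-205/33688028	NA	FALSE	nb	-100.63	NA
9	AG-205/36940103	1.7	FALSE	active	-105.53	0.149
10	AG-219/11789371	9.7	TRUE	active	-106.91	0.093
11	AG-219/12748006	NA	FALSE	nb	-99.60	NA
12	AG-690/11570086	NA	FALSE	nb	-114.9	NA
13	AG-690/40752975	2.6	FALSE	active	-98.67	0.127
14	AG-690/40753951	2.3	FALSE	active	-99.59	0.121
15	AH-487/40936254	7.3	FALSE	active	-110.82	0.140
16	AH-487/41654264	NA	FALSE	nb	-112.1	NA
17	AK-918/11909161	NA	FALSE	ns	-102.78	NA
18	AK-968/12162001	NA	FALSE	nb	-93.12	NA
19	AK-968/15253414	1.1	FALSE	active	-97.45	0.171
20	AK-968/15359742	NA	FALSE	nb	-98.30	NA
21	AK-968/15607331	10.7	TRUE	active	-117.16	0.131
22	AK-968/15608930	NA	FALSE	nb	-99.75	NA
23	AK-968/41022069	NA	FALSE	nb	-104.65	NA
24	AN-648/15596220	3.8	FALSE	active	-110.34	0.462
25	AN-989/41838307	2.4	FALSE	active	-108.44	0.109
26	AN-989/41838397	3.2	FALSE	active	-113.62	0.114
27	AO-081/15386326	NA	FALSE	nb	-107.94	NA
28	AO-081/15386957	NA	FALSE	nb	-103.42	NA
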