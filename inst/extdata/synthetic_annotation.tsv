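gene_id	length_nt	cog_class	is_regulator
cg0001	679	M	FALSE
cg0002	978	K	FALSE
cg0003	618	J	FALSE
cg0004	1845	S	FALSE
cg0005	1044	C	TRUE
cg0006	622	E	FALSE
cg0007	1121	G	FALSE
cg0008	1255	C	FALSE
cg0009	1166	K	FALSE
cg0010	784	S	FALSE
cg0011	1777	J	FALSE
cg0012	1073	L	FALSE
cg0013	681	J	FALSE
cg0014	332	L	FALSE
cg0015	1493	K	FALSE
cg0016	882	M	FALSE
cg0017	893	C	TRUE
cg0018	1376	M	FALSE
cg0019	1302	G	FALSE
cg0020	1176	T	FALSE
cg0021	1361	P	FALSE
cg0022	1280	C	FALSE
cg0023	931	J	FALSE
cg0024	368	J	FALSE
cg0025	1190	P	FALSE
cg0026	878	L	FALSE
cg0027	839	K	FALSE
cg0028	464	S	FALSE
cg0029	726	L	FALSE
cg0030	1086	M	FALSE
cg0031	1659	M	FALSE
cg0032	859	T	FALSE
cg0033	1072	J	FALSE
cg0034	878	C	FALSE
cg0035	484	T	FALSE
cg0036	747	G	FALSE
cg0037	754	C	FALSE
cg0038	876	P	FALSE
cg0039	1476	E	FALSE
cg0040	1269	G	FALSE
cg0041	836	J	FALSE
cg0042	803	T	FALSE
cg0043	1232	K	FALSE
cg0044	1156	T	FALSE
cg0045	660	P	FALSE
cg0046	655	G	TRUE
cg0047	1060	E	FALSE
cg0048	1272	T	FALSE
cg0049	856	K	FALSE
cg0050	1338	T	FALSE
cg0051	1077	T	FALSE
cg0052	683	M	FALSE
cg0053	1049	T	FALSE
cg0054	541	G	FALSE
cg0055	1715	T	FALSE
cg0056	2194	S	FALSE
cg0057	763	G	FALSE
cg0058	563	G	FALSE
cg0059	1163	M	FALSE
cg0060	847	K	FALSE
cg0061	2652	L	FALSE
cg0062	884	J	FALSE
cg0063	1228	K	FALSE
cg0064	911	L	FALSE
cg0065	644	G	FALSE
cg0066	980	E	FALSE
cg0067	399	K	TRUE
cg0068	1740	T	FALSE
cg0069	964	S	FALSE
cg0070	2392	T	FALSE
cg0071	1115	K	FALSE
cg0072	654	K	FALSE
cg0073	1185	M	FALSE
cg0074	591	C	FALSE
cg0075	512	G	FALSE
cg0076	1026	K	FALSE
cg0077	737	M	FALSE
cg0078	900	T	FALSE
cg0079	931	G	TRUE
cg0080	690	S	FALSE
cg0081	697	P	FALSE
cg0082	847	E	FALSE
cg0083	1529	T	FALSE
cg0084	453	G	FALSE
cg0085	1176	G	FALSE
cg0086	1045	P	FALSE
cg0087	1452	E	FALSE
cg0088	785	P	FALSE
cg0089	1063	L	FALSE
cg0090	1015	P	FALSE
cg0091	705	E	FALSE
cg0092	1550	L	FALSE
cg0093	1517	L	FALSE
cg0094	1233	E	FALSE
cg0095	1838	L	TRUE
cg0096	1157	T	FALSE
cg0097	507	M	TRUE
cg0098	695	C	FALSE
cg0099	519	C	FALSE
cg0100	727	L	FALSE
cg0101	681	P	FALSE
cg0102	917	P	FALSE
cg0103	597	S	FALSE
cg0104	966	S	FALSE
cg0105	670	G	FALSE
cg0106	1994	S	FALSE
cg0107	1243	S	FALSE
cg0108	1356	M	FALSE
cg0109	1070	K	FALSE
cg0110	1919	L	FALSE
cg0111	676	P	FALSE
cg0112	731	K	FALSE
cg0113	1715	M	FALSE
cg0114	672	E	FALSE
cg0115	820	M	FALSE
cg0116	754	S	FALSE
cg0117	779	S	FALSE
cg0118	794	E	FALSE
cg0119	1124	G	FALSE
cg0120	831	J	FALSE
cg0121	717	J	FALSE
cg0122	1647	G	FALSE
cg0123	817	G	FALSE
cg0124	830	S	FALSE
cg0125	860	G	FALSE
cg0126	1240	T	FALSE
cg0127	871	J	FALSE
cg0128	885	P	FALSE
cg0129	662	G	FALSE
cg0130	778	J	FALSE
cg0131	925	S	FALSE
cg0132	690	L	FALSE
cg0133	1143	P	FALSE
cg0134	454	E	FALSE
cg0135	1033	G	FALSE
cg0136	451	P	FALSE
cg0137	786	S	FALSE
cg0138	710	P	FALSE
cg0139	671	E	FALSE
cg0140	877	M	FALSE
cg0141	380	L	FALSE
cg0142	1528	S	FALSE
cg0143	425	J	FALSE
cg0144	731	E	FALSE
cg0145	545	E	FALSE
cg0146	642	C	FALSE
cg0147	2302	T	FALSE
cg0148	907	K	FALSE
cg0149	504	S	FALSE
cg0150	430	K	FALSE
cg0151	1102	K	FALSE
cg0152	893	G	FALSE
cg0153	780	S	FALSE
cg0154	592	T	TRUE
cg0155	461	M	TRUE
cg0156	555	L	FALSE
cg0157	1411	E	FALSE
cg0158	680	J	FALSE
cg0159	483	T	FALSE
cg0160	2087	G	FALSE
cg0161	1090	G	FALSE
cg0162	808	T	FALSE
cg0163	1449	L	FALSE
cg0164	1341	P	FALSE
cg0165	681	K	FALSE
cg0166	2429	M	FALSE
cg0167	802	S	FALSE
cg0168	474	G	FALSE
cg0169	843	T	FALSE
cg0170	988	S	FALSE
cg0171	2543	M	FALSE
cg0172	944	E	FALSE
cg0173	1105	M	FALSE
cg0174	869	M	FALSE
cg0175	774	M	FALSE
cg0176	886	S	FALSE
cg0177	1283	K	FALSE
cg0178	2290	C	FALSE
cg0179	1429	C	FALSE
cg0180	1550	T	FALSE
cg0181	517	L	FALSE
cg0182	1401	T	FALSE
cg0183	994	C	FALSE
cg0184	465	P	FALSE
cg0185	1138	T	FALSE
cg0186	838	L	FALSE
cg0187	1740	G	FALSE
cg0188	638	E	FALSE
cg0189	742	E	TRUE
cg0190	593	M	FALSE
cg0191	831	T	FALSE
cg0192	1078	S	FALSE
cg0193	647	L	FALSE
cg0194	1308	S	FALSE
cg0195	523	L	FALSE
cg0196	562	T	FALSE
cg0197	1721	L	FALSE
cg0198	570	L	FALSE
cg0199	1083	S	FALSE
cg0200	758	K	FALSE
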