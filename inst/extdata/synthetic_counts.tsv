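gene_id	S1	S2	S3	S4	S5	S6
cg0001	11284	18104	10738	13978	13772	10832
cg0002	128590	121956	84841	88827	98494	104258
cg0003	37100	38970	60116	62103	44043	49309
cg0004	15806	11552	9187	13278	12014	13170
cg0005	538	761	394	432	625	610
cg0006	154238	155069	152693	124682	255079	127601
cg0007	29341	26874	28170	33309	25965	26093
cg0008	33950	36336	24909	37952	39709	25585
cg0009	15695	12781	11986	9483	15751	12363
cg0010	17019	16820	14058	10473	9454	16784
cg0011	18051	21026	15358	21368	11601	22545
cg0012	17528	21207	28444	27334	18657	17917
cg0013	4275	3544	4385	3722	5023	4296
cg0014	504	618	510	644	732	556
cg0015	74390	79134	68606	58554	78748	80771
cg0016	90054	66088	60554	64825	85571	88756
cg0017	6392	7476	7893	6917	6834	6153
cg0018	3364	3975	3353	2407	3122	2577
cg0019	22808	29261	37192	19285	34854	39943
cg0020	12107	16833	155933	190922	119038	135764
cg0021	1476	1211	1187	1743	1750	2330
cg0022	10928	12075	19036	11561	16547	12719
cg0023	5233	4644	3488	5435	4073	4920
cg0024	2982	3154	2525	3185	2105	3142
cg0025	2984	3714	2420	3335	2013	3435
cg0026	102614	99413	96091	82913	149655	97679
cg0027	4380	5685	428	330	429	529
cg0028	721	752	669	742	666	497
cg0029	11558	8243	11426	11454	8413	11381
cg0030	16455	12618	21049	17614	20717	17556
cg0031	5303	7598	368	319	368	569
cg0032	219	212	205	253	133	250
cg0033	6853	7385	5263	2955	5744	4652
cg0034	19657	23056	21378	19655	31267	21683
cg0035	5463	4738	4814	4961	6109	6746
cg0036	6898	6100	1559	1290	1289	1556
cg0037	22838	23242	11471	15063	15618	16441
cg0038	2714	1408	1727	2005	2115	1757
cg0039	95623	97734	62737	40497	96464	47920
cg0040	10322	9352	11660	9195	16430	11419
cg0041	29130	26387	25445	20758	21293	20921
cg0042	28457	33454	27720	39643	38556	25984
cg0043	14197	16311	17045	17734	12578	18063
cg0044	4877	4339	4739	4731	2482	3501
cg0045	36718	35918	35094	28088	29402	39749
cg0046	468	487	660	562	530	659
cg0047	5737	3388	1618	1223	1113	1309
cg0048	9334	11449	12447	11107	7749	9348
cg0049	8602	6950	6448	9615	6510	7694
cg0050	55114	65158	53035	66084	86893	63891
cg0051	13537	18776	8380	15888	9325	9001
cg0052	15114	17092	1363	2110	2116	1610
cg0053	7892	12158	9089	7193	14005	10596
cg0054	3952	2941	3917	3740	4224	3740
cg0055	32265	52197	46254	51665	48481	47439
cg0056	101163	147914	125147	98875	113182	73274
cg0057	371	418	341	198	342	316
cg0058	12233	13275	17174	9106	9888	13470
cg0059	17900	20865	25740	19517	23056	16210
cg0060	5368	7922	4077	5486	5004	5272
cg0061	138250	45474	6762	12412	13444	12763
cg0062	5597	6968	6143	4234	4447	7731
cg0063	9037	10298	9042	6562	10837	7473
cg0064	26742	25142	44148	44666	29744	27789
cg0065	73817	62428	70496	74739	77011	83615
cg0066	22141	16074	18754	18763	19397	14471
cg0067	2976	1892	202	126	217	265
cg0068	2858	2907	2526	3341	3603	4297
cg0069	11148	5529	9545	9419	4695	7745
cg0070	8700	5824	8487	5191	6417	6698
cg0071	9986	6602	7926	8046	7234	7537
cg0072	18739	9315	15137	9652	15200	10984
cg0073	5557	5488	4614	4340	5202	5737
cg0074	179232	160940	199696	178218	175707	198568
cg0075	6981	5955	8572	4081	6405	6678
cg0076	41756	50378	48114	42770	47043	49343
cg0077	426	491	365	581	404	528
cg0078	22295	24610	24197	27882	24677	25374
cg0079	2661	1747	1473	1582	1399	1140
cg0080	19881	19371	23399	23063	28803	18279
cg0081	14501	11811	13314	10035	11130	12169
cg0082	7720	7836	5174	6771	5807	7269
cg0083	132019	90433	99441	110412	79905	93088
cg0084	2289	2498	208	239	169	215
cg0085	6893	5782	515	755	631	782
cg0086	2387	4044	3211	3051	4224	2900
cg0087	8591	5607	87352	95276	125167	81416
cg0088	21814	23590	25350	16904	20337	26043
cg0089	13509	25221	31066	25174	20025	26902
cg0090	39820	38548	31899	34229	44166	26695
cg0091	4478	3729	6205	4500	6273	3240
cg0092	43967	21856	19169	23574	25294	35045
cg0093	33087	22202	17628	25160	22899	30623
cg0094	3049	3690	2737	2191	1928	2228
cg0095	261841	163901	160638	206862	223587	168843
cg0096	12083	12822	12608	16451	16889	15929
cg0097	12298	14908	1319	750	1030	1186
cg0098	23637	24895	19589	20852	25260	30446
cg0099	6764	5987	5834	6126	8003	4306
cg0100	5964	5060	4973	3681	5365	6264
cg0101	30343	30904	35553	15383	29861	15468
cg0102	2604	3287	2549	2642	1954	3012
cg0103	93842	124386	70064	74443	82671	87539
cg0104	7295	8604	6810	4073	6376	7251
cg0105	77818	48487	59955	55882	65309	63627
cg0106	168717	194849	165712	146197	155177	263875
cg0107	9947	15081	12454	12136	9848	14288
cg0108	44943	32592	25937	26196	39973	30304
cg0109	5341	3709	3842	2719	3169	3439
cg0110	41027	21273	30863	40212	32194	37467
cg0111	27517	35280	21842	23927	25972	22526
cg0112	10100	11558	826	986	542	527
cg0113	11922	8105	6250	7334	7398	6946
cg0114	4556	3914	3067	3114	3218	2241
cg0115	10755	8347	6846	5659	9448	14443
cg0116	41855	25635	38796	37976	34906	29362
cg0117	2855	6053	4203	6245	4838	5896
cg0118	8484	6623	5983	7485	7193	10650
cg0119	2863	2682	1375	2224	1853	2368
cg0120	17014	15891	13716	14383	23225	10965
cg0121	65348	51506	48061	47033	36910	45977
cg0122	176690	67992	150110	194446	129092	140421
cg0123	29622	23544	21179	22154	34767	28609
cg0124	552	990	698	571	1043	874
cg0125	16215	18327	13978	20726	15572	18797
cg0126	34491	25802	18059	26950	25888	21996
cg0127	5859	6981	5103	4714	5116	5447
cg0128	16450	10861	12065	11081	9217	11456
cg0129	2768	2955	1653	2586	3108	2574
cg0130	29328	18309	16417	21065	22219	20893
cg0131	6271	7133	5271	5537	6490	7345
cg0132	1300	698	1314	863	1482	1143
cg0133	8511	10199	1935	1668	1323	2088
cg0134	24556	44306	22476	37610	27969	25619
cg0135	9157	5952	5435	5394	7491	10221
cg0136	11970	8881	9274	9041	12460	13920
cg0137	23248	41553	29922	27024	20359	40207
cg0138	7518	6766	7349	7551	5954	7908
cg0139	5021	3428	2923	3951	3905	4391
cg0140	3996	6017	5808	5662	5648	6022
cg0141	12909	16253	7490	11972	7590	9221
cg0142	4133	2806	6807	3167	3992	2712
cg0143	6413	6415	7282	4651	8834	6645
cg0144	4177	5998	4394	5053	6961	3387
cg0145	380	412	237	339	333	254
cg0146	1143	1226	1368	1202	1221	934
cg0147	98239	90704	82413	119003	115665	81959
cg0148	6764	7862	67394	81165	94439	96205
cg0149	16906	17433	21272	14963	14387	19167
cg0150	69003	44149	44510	38788	49779	51795
cg0151	109539	88795	70267	124024	87439	92107
cg0152	23149	22386	20577	18432	28624	29496
cg0153	17969	16488	17045	20690	9953	14025
cg0154	5915	4115	6401	5246	3186	3708
cg0155	49369	35342	40750	36070	34506	30950
cg0156	12818	14138	19299	13185	12373	15515
cg0157	3871	3205	2936	3140	2821	2033
cg0158	6631	6599	5084	7525	8606	9752
cg0159	301	372	558	323	455	523
cg0160	15223	18967	20951	16724	18441	22051
cg0161	602	390	438	198	569	338
cg0162	69209	60428	6265	10682	7520	5277
cg0163	6516	10618	6610	8270	8205	7093
cg0164	11518	13696	5633	5873	7581	6817
cg0165	6365	4576	6813	4281	10601	6851
cg0166	38003	47445	59292	57031	50752	68899
cg0167	28831	32809	15636	20444	21974	17108
cg0168	11689	6961	10980	8943	7468	8133
cg0169	4412	4414	3639	3781	5440	3645
cg0170	1863	1840	2100	2115	2086	1892
cg0171	15482	14600	15256	21302	15921	13004
cg0172	9533	13843	18377	13398	14399	14087
cg0173	3558	3368	4104	3436	4205	3376
cg0174	9419	13917	7824	5328	8681	9047
cg0175	2295	1823	2089	1738	1758	1626
cg0176	8620	8675	9700	7015	6110	11240
cg0177	23814	16186	2775	2091	1979	2111
cg0178	25177	18785	20329	26488	23906	25389
cg0179	11500	12773	10779	6593	15086	11404
cg0180	127845	118390	170528	126001	97546	184839
cg0181	18112	8667	10889	13718	12018	15554
cg0182	143203	73621	73634	87705	71177	60486
cg0183	2254	2726	2579	3789	3570	3971
cg0184	8470	5414	349	381	295	384
cg0185	36675	64248	70923	49147	45450	53677
cg0186	8730	8866	7385	6097	7045	10847
cg0187	1054	1223	917	1158	920	1197
cg0188	10834	9614	12569	10251	13853	12238
cg0189	672	571	901	673	543	756
cg0190	2993	2648	2855	1700	2565	2123
cg0191	66074	46429	66170	61972	39977	39578
cg0192	26607	27488	196886	407164	290503	294867
cg0193	26672	37661	26502	13772	28776	23212
cg0194	24939	18586	19627	13148	13205	19406
cg0195	7216	6346	5288	5325	5359	6350
cg0196	2063	1250	1401	1504	1623	1255
cg0197	143732	161087	135113	110437	148638	141036
cg0198	13698	8311	9219	5581	6108	5657
cg0199	3938	2521	5863	6362	3349	3904
cg0200	21237	24697	5208	6457	4479	5261
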