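sample_id	CHEBI:00001	CHEBI:00002	CHEBI:00003	CHEBI:00004	CHEBI:00005	CHEBI:00006	CHEBI:00007	CHEBI:00008	CHEBI:00009	CHEBI:00010	CHEBI:00011	CHEBI:00012	CHEBI:00013	CHEBI:00014	CHEBI:00015	CHEBI:00016	CHEBI:00017	CHEBI:00018	CHEBI:00019	CHEBI:00020	CHEBI:00021	CHEBI:00022	CHEBI:00023	CHEBI:00024	CHEBI:00025	CHEBI:00026	CHEBI:00027	CHEBI:00028	CHEBI:00029	CHEBI:00030
sample_001	NA	390.708	4688.19	2009.65	831.062	1352.21	1675.67	4482.66	3841.38	575.957	371.67	4278.59	457.59	125.375	2020.8	1764.36	1323.75	628.742	489.657	872.868	642.773	5793.96	NA	454.624	350.689	308.819	191.957	1927.89	258.138	18291.7
sample_002	121.748	1488.03	211.683	72.7721	119.089	1359.32	196.931	310.09	294.758	438.388	954.263	917.624	2833.02	917.273	409.362	1319.12	121.283	1525.2	251.654	174.003	67.9658	708.819	1329.47	462.722	2168.69	129.021	360.551	1330.38	140.983	148.124
sample_003	2980.64	3325.46	584.831	NA	1194.11	162.34	2352.23	7112.28	379.992	1398.05	NA	922.581	936.073	1103.31	1474.26	289.445	1587.53	3332.41	4944.39	826.141	866.223	86.5434	792.422	179.888	960.427	419.757	301.395	1124.99	NA	4654.43
sample_004	14157.9	1301.68	28651.7	39.9112	2429.29	2187.56	21403.6	11872.9	16296.8	123.351	1092.7	2315.18	188.069	292.096	15058.7	1361.07	545.488	1697.46	2063.42	214.084	1927.05	572.146	231.885	237.03	507.635	1030.99	738.822	804.031	3304.61	2262.56
sample_005	4581.68	535.883	3007.38	52.778	380.759	411.312	645.572	6514.79	622.683	543.072	175.479	240.928	509.264	290.708	1525.58	10822.5	30.2017	558.166	1502.07	4088.24	1649.56	685.793	733.247	NA	61.338	462.706	229.523	482.32	1136.34	2612.07
sample_006	NA	375.424	500.567	175.522	202.766	2652.97	67.5814	82.3366	66.8197	6045.94	3311.81	2306.23	NA	647.483	NA	4180.1	478.341	3033.21	160.733	456.334	NA	2071.52	493.514	NA	739.034	NA	132.226	495.028	674.371	370.991
sample_007	370.897	44.3523	634.254	146.336	685.137	478.421	4699.13	602.825	427.153	520.021	4484.15	1876.28	437.454	334.286	1308.12	458.145	572.765	380.706	517.752	808.777	1595.83	159.219	520.83	2454.96	833.087	2228.67	983.761	442.078	478.539	398.122
sample_008	184.276	975.651	1764.17	172.839	2192.22	2922.37	19810.4	2072.35	14859.3	1338.15	5647.45	1974.34	2376.62	4449.2	177.443	5069.49	411.286	2429.04	329.627	1073.15	1508.49	83.6768	3451.05	979.103	3271.67	1488.47	1974.06	1607.16	1471.49	2493.55
sample_009	2520.12	258.071	211.782	1290.75	409.326	422.613	157.4	286.017	144.145	1647.89	2709.7	909.763	459.558	8936.19	669.117	NA	1127.65	850.786	121.58	102.284	356.191	254.124	146.357	1253.24	2208.22	294.979	358.868	298.526	391.081	107.925
sample_010	2522.31	1348.42	977.981	1854.92	251.697	279.507	412.771	2012.54	113.578	377.04	16120.9	383.054	7446.54	2435.97	2639.6	1125.32	822.173	178.035	798.183	2162.69	993.434	430.636	7637.83	3230.56	510.683	1303.59	460.771	169.896	147.592	1514.38
sample_011	10449.5	2630.55	1667.4	5267.47	1217.54	6512.67	682.792	815.926	437.416	770.533	208.353	151.279	1048.34	265.785	NA	1541.84	22565.4	746.686	1897.52	9331.13	422.367	89.7513	1464.34	1468.24	NA	369.416	1575.06	601.45	2590.57	302.77
sample_012	1726.98	169.035	3931.64	1325.19	750.972	149.511	4434.23	1758.34	1254.41	1120.46	698.088	10012.7	8384.15	1255.86	438.846	153.781	138.166	982.196	553.924	1222.35	5679.91	1933.57	1329.32	1136.35	1626.92	421.092	953.427	791.24	344.161	238.665
sample_013	1077.26	3402.25	328.788	1222.7	1341.84	4626.28	725.168	923.799	1160.25	849.463	14110.9	4034.13	456.261	64.7471	NA	475.478	1228.75	348.114	480.335	531.738	6589.04	3200.08	908.782	12339.1	8578.97	610.887	2527.15	174.861	3438.03	179.849
sample_014	860.155	26584.5	3723.8	1526.58	2548.4	1879.39	1409.98	561.065	633.921	306.681	640.888	25515.2	1548.61	4907.92	NA	441.044	4549.34	423.545	2618.51	3311.98	2273.77	3530.89	17218.6	3794.4	2655.34	4513.17	223.274	778.898	39564.3	506.562
sample_015	194.823	565.555	2231.77	1946.22	487.64	2108.49	256.43	1358.95	634.401	1020.69	313.726	3863.37	5805.43	4420.01	252.662	136.591	2042.07	879.355	100.582	386.553	19143	2543.16	4915.35	255.888	1675.91	4922.57	2741.77	452.938	2222.92	3197.6
sample_016	524.294	744.847	2285.9	11302.8	1677.98	2560.08	2820.46	16190.5	NA	633.674	487.926	728.146	184.43	334592	NA	699.436	3919.07	187.662	222.334	1524.39	3072.95	9228.16	10104.3	NA	812.794	648.726	1733.54	2070.93	2790.32	1500.98
sample_017	NA	3013.59	4136.54	11877	11302.6	2161	6010.11	4381.97	1343.57	59.5451	1055.46	1634.53	123.364	2811.12	93.0354	161.035	90.7455	142.122	599.956	262.276	1169.6	813.173	810.793	679.933	1406.22	737.118	330.834	619.853	466.1	1009.32
sample_018	1533.65	14224.7	2353.48	1195.57	1350.83	192.675	2673.32	3475.92	5980.01	NA	393.246	1514.37	105.533	356.684	7871.17	129.188	250.829	167.085	85.6288	7880.51	7515.97	832.715	1102.19	97.1747	45.6595	140.055	4463.4	753.734	690.585	947.063
sample_019	3917.85	5270.14	3625.28	NA	2997.29	4002.9	1318.04	228.757	7997.2	3727.69	2206.28	NA	2248.62	296.081	1291.49	6289.16	2575.42	2441.55	12208.7	406.975	1361.36	1883.96	129.987	3553.35	710.626	388.52	1474.04	3571.38	746.605	13121.8
sample_020	844.115	3815.65	15461.8	4962.12	7032.88	6635.93	5766.13	280.737	351.052	4378.65	1575.25	1626.43	54.704	1716.76	953.887	NA	894.898	59.4991	861.715	12044.9	3473.08	292.721	208.026	119.386	1502.85	473.349	536.558	751.775	2672.07	367.845
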