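	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0.1497	0.2027	0.0604	0.2099	0.027	0.1857	0.8407	0.1608	0.1569	0.0368	0.1726	0.1498	0.0472	0.7633	0.0602	0.1655	0.2277	0.0236	0.0452	0.8939
C	0.1847	0.0877	0.1811	0.1213	0.2065	0.2179	0.0618	0.2169	0.1822	0.0331	0.1771	0.1604	0.2416	0.1864	0.2379	0.1326	0.1082	0.0545	0.2083	0.2486
D	0.1018	0.0793	0.1362	0.0546	0.0948	0.1328	0.6661	0.1312	0.1281	0.0665	0.2186	0.2154	0.2487	0.1273	0.0331	0.1816	0.209	0.1836	0.0717	0.0711
E	0.0752	0.6476	0.1561	0.0932	0.236	0.1551	0.8374	0.2348	0.0461	0.1376	0.0643	0.1184	0.2389	0.1068	0.7739	0.1929	0.0924	0.0203	0.2423	0.0589
F	0.1146	0.1212	0.2246	0.8659	0.1088	0.2325	0.0278	0.1396	0.1666	0.1286	0.0204	0.1552	0.0598	0.1185	0.0122	0.1617	0.0609	0.852	0.1998	0.1721
G	0.0463	0.0827	0.1603	0.0903	0.2278	0.1908	0.1295	0.1961	0.0737	0.1308	0.1927	0.1263	0.016	0.8144	0.0418	0.7695	0.1183	0.176	0.0857	0.1188
H	0.0542	0.179	0.1799	0.0651	0.2393	0.127	0.0516	0.0503	0.1988	0.0548	0.0853	0.0569	0.7719	0.0783	0.1661	0.6046	0.0954	0.0954	0.0791	0.1439
I	0.0833	0.2357	0.2136	0.134	0.1393	0.0269	0.1886	0.9319	0.0124	0.1612	0.6983	0.0145	0.2481	0.2477	0.1642	0.1387	0.1624	0.1191	0.2141	0.2376
K	0.2289	0.1462	0.2461	0.0276	0.1136	0.1774	0.2206	0.0332	0.0817	0.152	0.0979	0.2059	0.132	0.2183	0.0949	0.2212	0.1962	0.2364	0.0524	0.064
L	0.0821	0.1096	0.1364	0.0481	0.1948	0.19	0.0273	0.129	0.1943	0.0144	0.2471	0.2326	0.1667	0.1493	0.0523	0.0557	0.1896	0.1983	0.7212	0.1417
M	0.1031	0.1806	0.1836	0.1004	0.1958	0.0101	0.1665	0.2495	0.0603	0.034	0.0826	0.2135	0.1861	0.1266	0.08	0.0585	0.2441	0.128	0.1131	0.1656
N	0.7358	0.2262	0.0367	0.2102	0.0991	0.2037	0.0824	0.0312	0.0522	0.2099	0.2366	0.7009	0.6266	0.1407	0.1429	0.2266	0.2245	0.1434	0.1752	0.1947
P	0.0109	0.1157	0.0636	0.1386	0.0306	0.2026	0.1965	0.2301	0.0494	0.0188	0.0437	0.0107	0.1947	0.0996	0.1782	0.0531	0.0385	0.0104	0.1716	0.1639
Q	0.1087	0.1264	0.2092	0.1136	0.0867	0.2193	0.7317	0.0127	0.1636	0.1051	0.1753	0.0451	0.0303	0.1114	0.0856	0.1706	0.2224	0.2101	0.6723	0.9414
R	0.1346	0.0285	0.0798	0.1916	0.8126	0.1706	0.1429	0.7034	0.1079	0.1697	0.2253	0.0766	0.2018	0.2119	0.1392	0.1758	0.0812	0.2404	0.1367	0.0428
S	0.1297	0.2366	0.0765	0.1498	0.7666	0.2071	0.2033	0.2095	0.1007	0.1941	0.2267	0.2197	0.0872	0.0985	0.0345	0.2117	0.0239	0.0636	0.1509	0.1394
T	0.1599	0.2498	0.0623	0.1615	0.1421	0.0943	0.1071	0.1972	0.1237	0.1058	0.1571	0.0943	0.1957	0.1999	0.1187	0.1221	0.0805	0.0171	0.0762	0.0334
V	0.2149	0.8799	0.13	0.1336	0.249	0.229	0.2405	0.0237	0.0241	0.1902	0.0348	0.1544	0.083	0.2397	0.2492	0.8038	0.0897	0.0876	0.1223	0.1734
W	0.1485	0.154	0.2489	0.2143	0.0424	0.194	0.0903	0.1998	0.2378	0.1258	0.0769	0.0274	0.1756	0.0643	0.0307	0.0143	0.2244	0.1536	0.2251	0.8821
Y	0.1229	0.1309	0.0903	0.1998	0.1606	0.0243	0.0101	0.1404	0.1262	0.0581	0.0651	0.0257	0.0607	0.1196	0.083	0.1595	0.1853	0.1072	0.0577	0.1726
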