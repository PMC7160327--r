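	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0.1065	0.2064	0.2023	0.0614	0.0482	0.0828	0.0635	0.1569	0.1023	0.0584	0.0553	0.084	0.0947	0.1801	0.2113	0.2083	0.0566	0.0546	0.2054	0.1623
C	0.1622	0.1905	0.8614	0.2026	0.0442	0.1438	0.023	0.0921	0.0163	0.1903	0.0689	0.0805	0.6396	0.0182	0.162	0.2347	0.1853	0.0167	0.619	0.0755
D	0.1865	0.0488	0.2133	0.0993	0.1561	0.0376	0.186	0.2232	0.2397	0.1056	0.2152	0.2073	0.0821	0.093	0.1271	0.0918	0.2436	0.2196	0.0252	0.1663
E	0.0665	0.0116	0.0355	0.0913	0.0749	0.0731	0.12	0.8526	0.195	0.032	0.1507	0.1154	0.2189	0.8212	0.1865	0.2385	0.1211	0.0771	0.2204	0.1847
F	0.2369	0.2129	0.0587	0.1428	0.0389	0.0197	0.1257	0.0906	0.0943	0.0269	0.114	0.749	0.07	0.0421	0.1519	0.0437	0.0357	0.1642	0.0313	0.7772
G	0.1944	0.1191	0.2335	0.2463	0.2237	0.2285	0.1457	0.1819	0.0647	0.1844	0.2417	0.0371	0.0377	0.1782	0.0703	0.2132	0.0874	0.1075	0.2317	0.021
H	0.113	0.2328	0.6867	0.0972	0.0737	0.1778	0.1511	0.0432	0.119	0.202	0.1398	0.0447	0.2178	0.2436	0.236	0.1027	0.1588	0.1879	0.1344	0.1602
I	0.9257	0.1178	0.2365	0.2333	0.1966	0.2111	0.0669	0.1392	0.2017	0.0588	0.2143	0.1368	0.9399	0.2209	0.1661	0.1107	0.1979	0.0372	0.0986	0.1994
K	0.1307	0.0895	0.0378	0.0632	0.111	0.2197	0.214	0.0964	0.0398	0.0277	0.6665	0.0269	0.0896	0.1539	0.1859	0.0469	0.1462	0.0731	0.0447	0.2107
L	0.2156	0.1353	0.2483	0.0413	0.0144	0.1169	0.2239	0.0791	0.2146	0.2337	0.1667	0.8714	0.141	0.0569	0.8594	0.045	0.2347	0.1254	0.1937	0.1695
M	0.645	0.1684	0.0406	0.1936	0.2182	0.2252	0.1505	0.1341	0.0181	0.1256	0.188	0.0711	0.0534	0.1057	0.0297	0.1321	0.1433	0.6128	0.1725	0.0531
N	0.2191	0.1377	0.2025	0.077	0.172	0.2147	0.2289	0.1003	0.104	0.1049	0.1685	0.9259	0.083	0.1755	0.2174	0.1179	0.1771	0.8383	0.1548	0.6168
P	0.2409	0.1519	0.0902	0.1385	0.116	0.1104	0.0156	0.234	0.0351	0.6054	0.1991	0.1312	0.0224	0.1761	0.2416	0.1421	0.0651	0.041	0.156	0.0766
Q	0.2203	0.1038	0.1891	0.0296	0.2485	0.1372	0.2315	0.18	0.0886	0.2274	0.1714	0.0271	0.0922	0.7719	0.1851	0.1031	0.0485	0.7984	0.1028	0.0117
R	0.0271	0.1104	0.0713	0.2044	0.1269	0.9463	0.127	0.0118	0.0762	0.1123	0.0863	0.1264	0.0239	0.1109	0.0738	0.0621	0.1081	0.0116	0.2118	0.1951
S	0.0923	0.7427	0.0747	0.8146	0.2399	0.0815	0.1755	0.0872	0.2159	0.2187	0.0511	0.1243	0.1216	0.6797	0.1139	0.8143	0.2068	0.0512	0.0817	0.1479
T	0.216	0.078	0.2236	0.1114	0.1678	0.1059	0.0257	0.1911	0.1654	0.0306	0.0138	0.1287	0.1582	0.0579	0.1636	0.2069	0.1016	0.1724	0.065	0.1926
V	0.1251	0.0997	0.0968	0.0895	0.0773	0.0661	0.0929	0.0873	0.153	0.1902	0.1356	0.0516	0.2436	0.7123	0.2332	0.0665	0.084	0.1359	0.0548	0.1721
W	0.1012	0.2302	0.1573	0.817	0.1839	0.0401	0.7867	0.2346	0.2214	0.0428	0.1524	0.1871	0.8142	0.0943	0.082	0.1578	0.0608	0.059	0.2474	0.1178
Y	0.2174	0.1231	0.0625	0.2442	0.2052	0.9243	0.1724	0.935	0.2472	0.1018	0.2364	0.156	0.2367	0.067	0.1492	0.0756	0.2149	0.1192	0.1862	0.218
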