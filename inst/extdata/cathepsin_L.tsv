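	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0.1686	0.2334	0.1876	0.1893	0.1314	0.0286	0.1052	0.0453	0.2029	0.2488	0.1884	0.0809	0.1556	0.0358	0.2264	0.0451	0.0121	0.2344	0.6429	0.0442
C	0.2125	0.1166	0.0192	0.0884	0.147	0.1056	0.0619	0.0188	0.0449	0.2302	0.1767	0.02	0.1272	0.0201	0.0631	0.1711	0.0117	0.0106	0.1683	0.0581
D	0.1948	0.012	0.2287	0.1232	0.1707	0.1831	0.222	0.8233	0.0925	0.0559	0.1813	0.1594	0.1598	0.2039	0.0171	0.1141	0.2274	0.7018	0.225	0.1079
E	0.1345	0.6437	0.1579	0.1251	0.1541	0.0206	0.2245	0.0611	0.0555	0.1602	0.1817	0.1396	0.1764	0.0324	0.2184	0.1561	0.1269	0.1836	0.6708	0.107
F	0.1125	0.117	0.041	0.134	0.1099	0.0109	0.2351	0.0601	0.1213	0.079	0.1214	0.1913	0.0614	0.1709	0.0212	0.0263	0.1895	0.1899	0.1602	0.0747
G	0.1944	0.0379	0.1329	0.1785	0.1596	0.225	0.2114	0.2032	0.1784	0.2444	0.1267	0.0647	0.1655	0.2464	0.1553	0.8538	0.2061	0.1622	0.0965	0.1561
H	0.1395	0.1717	0.1543	0.0342	0.0564	0.0895	0.1452	0.2115	0.2187	0.1558	0.2367	0.0833	0.1472	0.763	0.1926	0.0794	0.1539	0.0942	0.2004	0.0861
I	0.2443	0.2324	0.1032	0.1421	0.0711	0.1789	0.0972	0.1262	0.1008	0.2253	0.6837	0.2021	0.2329	0.0654	0.0166	0.0503	0.0883	0.131	0.2316	0.098
K	0.113	0.1749	0.1018	0.1279	0.7391	0.024	0.1898	0.2408	0.6747	0.1015	0.1981	0.2258	0.1271	0.0572	0.2008	0.1084	0.0948	0.0157	0.1084	0.0462
L	0.1596	0.039	0.6793	0.0922	0.7353	0.2275	0.0706	0.9109	0.1581	0.1654	0.1495	0.0844	0.1863	0.0122	0.0641	0.141	0.0448	0.1426	0.0563	0.0927
M	0.2489	0.0912	0.7172	0.9281	0.1533	0.0723	0.0178	0.044	0.0664	0.1945	0.2383	0.8631	0.1395	0.1511	0.6566	0.2025	0.0559	0.1804	0.8133	0.1009
N	0.1781	0.2103	0.1003	0.063	0.2031	0.0135	0.0369	0.0671	0.1663	0.2287	0.0944	0.072	0.23	0.1964	0.1687	0.2387	0.0596	0.6955	0.136	0.2349
P	0.1901	0.016	0.0506	0.0362	0.0821	0.1693	0.1027	0.2494	0.0658	0.0837	0.2337	0.1106	0.0485	0.0919	0.1627	0.19	0.2132	0.0128	0.1025	0.0862
Q	0.0733	0.1747	0.1612	0.069	0.0696	0.1815	0.0949	0.2285	0.1673	0.1121	0.0496	0.2055	0.0251	0.1444	0.0695	0.1176	0.0709	0.1124	0.1957	0.9252
R	0.0334	0.2129	0.1615	0.088	0.8162	0.1115	0.1802	0.0943	0.21	0.1799	0.1482	0.2128	0.0427	0.1865	0.1076	0.034	0.7562	0.0509	0.1389	0.0205
S	0.078	0.0271	0.2073	0.1665	0.1811	0.0888	0.2333	0.2118	0.1236	0.0759	0.0569	0.108	0.1812	0.0931	0.1892	0.1479	0.1164	0.1439	0.2039	0.8202
T	0.2388	0.1008	0.1008	0.1581	0.0196	0.0202	0.1712	0.7849	0.1789	0.0109	0.0749	0.0734	0.1677	0.0126	0.087	0.2423	0.1135	0.1144	0.1772	0.0368
V	0.0121	0.0804	0.0465	0.1066	0.1188	0.1653	0.2059	0.2343	0.0281	0.1562	0.0832	0.1653	0.1779	0.2154	0.0922	0.1895	0.2004	0.1004	0.045	0.2429
W	0.0514	0.0905	0.0101	0.0264	0.245	0.0563	0.2189	0.2107	0.0265	0.8185	0.0576	0.1568	0.2302	0.2105	0.2168	0.7579	0.2332	0.1346	0.1208	0.8243
Y	0.0319	0.1811	0.0885	0.0197	0.2051	0.123	0.0381	0.1457	0.1272	0.1889	0.2293	0.0709	0.2461	0.0208	0.0401	0.692	0.0774	0.1149	0.1843	0.1082
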