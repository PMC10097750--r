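gene_id	chrom	starts	ends	subtelomeric_printed
SPNCRNA.602	I	50851	51545	TRUE
SPAC1F8.04c	I	92387	93931	TRUE
SPNCRNA.607	I	99046	101140	TRUE
SPAC11D3.19	I	106893	108361	TRUE
SPAC11D3.03c	I	110904;112098;112378	112046;112333;112499	TRUE
SPAC11D3.16c	I	140381	141653	TRUE
SPAC11D3.17	I	141199;141559	141510;144768	TRUE
SPAC13G6.08	I	187701	190031	TRUE
SPNCRNA.643	I	388352	389177	FALSE
SPNCRNA.649	I	446175	446702	FALSE
SPAC23E2.03c	I	450860	453603	FALSE
SPNCRNA.673	I	664677	665246	FALSE
SPNCRNA.690	I	829234	831663	FALSE
SPNCRNA.220	I	1015475	1015830	FALSE
SPAC56F8.15	I	1151431	1153638	FALSE
SPNCRNA.737	I	1357621	1359568	FALSE
SPAC1002.19	I	1835270	1837060	FALSE
SPAC1399.03	I	1841908	1843995	FALSE
SPNCRNA.178	I	1844130	1845339	FALSE
SPAP11E10.02c	I	1856833	1860727	FALSE
SPAPB1A10.14	I	1890529	1892090	FALSE
SPAC3C7.02c	I	2064853	2066004	FALSE
SPNCRNA.791	I	2066217	2067343	FALSE
SPAC20H4.11c	I	2131685;2132545	2132426;2133066	FALSE
SPAC13F5.07c	I	2184654;2185472	2185282;2185990	FALSE
SPAC13G7.13c	I	2318492	2322664	FALSE
SPNCRNA.821	I	2380416	2381234	FALSE
SPAC22H10.13	I	2381690	2382200	FALSE
SPNCRNA.194	I	2424735	2425515	FALSE
SPNCRNA.43	I	2432340	2432921	FALSE
SPAC4A8.04	I	2544815	2546981	FALSE
SPNCRNA.835	I	2547093	2547449	FALSE
SPSNRNA.06	I	2562276;2562374	2562323;2562427	FALSE
SPNCRNA.198	I	2703965	2704030	FALSE
SPNCRNA.853	I	2784605	2785492	FALSE
SPNCRNA.860	I	2931622	2932800	FALSE
SPAC2E1P3.04	I	2931763	2935115	FALSE
SPAC31G5.09c	I	2999546	3001687	FALSE
SPNCRNA.71	I	3001761	3001930	FALSE
SPNCRNA.877	I	3032579	3033397	FALSE
SPAC24C9.16c	I	3042749;3042872;3043096;3043225	3042817;3042909;3043157;3043380	FALSE
SPAC3G9.11c	I	3159753	3162245	FALSE
SPAC6G10.06	I	3226929;3227042;3227456	3226980;3227383;3228192	FALSE
SPNCRNA.931	I	3731313	3732279	FALSE
SPNCRNA.935	I	3745778	3748833	FALSE
SPATRNAGLU.04	I	3776768	3776839	FALSE
SPNCRNA.955	I	4004553	4005632	FALSE
SPSNORNA.13	I	4154912	4155002	FALSE
SPAC25B8.13c	I	4179961	4183074	FALSE
SPAC1F7.06	I	4230615	4232557	FALSE
SPNCRNA.243	I	4231812	4232976	FALSE
SPAC9E9.17c	I	4437311;4437606;4437732;4437860	4437401;4437648;4437813;4437862	FALSE
SPNCRNA.987	I	4437466	4438921	FALSE
SPNCRNA.12	I	4439118	4439451	FALSE
SPAC17C9.16c	I	4472472;4473325	4473271;4474744	FALSE
SPAC27D7.03c	I	4510983	4515015	FALSE
SPNCRNA.993	I	4515182	4515993	FALSE
SPAC11H11.04	I	4780224	4781922	FALSE
SPAC4F10.17	I	4868326	4869283	FALSE
SPAC4F10.22	I	4878241	4878453	FALSE
SPAPB8E5.04c	I	4913971	4915513	FALSE
SPAPB8E5.05	I	4916603;4916921;4917286	4916841;4917214;4917521	FALSE
SPAPJ691.02	I	5187647	5189187	FALSE
SPAC19D5.07	I	5222447	5224795	FALSE
SPAC2H10.01	I	5273012	5275983	FALSE
SPNCRNA.1068	I	5309027	5311689	FALSE
SPNCRNA.1075	I	5353770	5354310	FALSE
SPAC1039.03	I	5452105	5453867	TRUE
SPAC1039.09	I	5465377	5468649	TRUE
SPAC1039.10	I	5470432;5470574;5471284	5470525;5471227;5471520	TRUE
SPAC922.09	I	5482662	5482877	TRUE
SPAC922.06	I	5485096	5486287	TRUE
SPNCRNA.1092	I	5495270	5496597	TRUE
SPAC869.09	I	5496844	5497448	TRUE
SPAC869.08	I	5497918	5499280	TRUE
SPAC869.07c	I	5499768	5501236	TRUE
SPAC869.06c	I	5502560	5503291	TRUE
SPAC869.04	I	5511137	5512369	TRUE
SPAC869.03c	I	5512757	5514865	TRUE
SPAC869.01	I	5521275	5523181	TRUE
SPBPB21E7.02c	II	60553;61119	61107;61205	TRUE
SPBPB21E7.10	II	61362;61632	61526;62126	TRUE
SPBPB21E7.11	II	61526;62598;62944	62449;62885;63086	TRUE
SPBC1683.05	II	147915	150574	TRUE
SPBC1271.09	II	350692;350787	350740;352369	FALSE
SPNCRNA.1346	II	359391	359866	FALSE
SPSNRNA.04	II	467233	467361	FALSE
SPNCRNA.1364	II	503961	505097	FALSE
SPBC1685.05	II	504397	509056	FALSE
SPNCRNA.66	II	547325	547761	FALSE
SPBC354.12	II	578063;578725	578181;580056	FALSE
SPBPJ4664.03	II	700291;700544	700476;700700	FALSE
SPNCRNA.1405	II	1013315	1014054	FALSE
SPNCRNA.1415	II	1150424	1150863	FALSE
SPSNORNA.21	II	1308634	1308745	FALSE
SPNCRNA.15	II	1329046	1329760	FALSE
SPBC83.19c	II	1541452	1541903	FALSE
SPNCRNA.352	II	1542196	1542364	FALSE
SPBC29B5.02c	II	1550293	1553467	FALSE
SPNCRNA.1443	II	1554843	1557638	FALSE
SPBC1D7.02c	II	1752100	1755619	FALSE
SPBC9B6.03	II	1817454	1819848	FALSE
SPBC23G7.11	II	2120231	2121050	FALSE
SPNCRNA.1512	II	2417501	2418682	FALSE
SPNCRNA.1525	II	2543249	2544500	FALSE
SPNCRNA.1530	II	2580400	2581182	FALSE
SPBC25B2.08	II	2611366	2612917	FALSE
SPBC19C7.04c	II	2825251	2826700	FALSE
SPNCRNA.1564	II	2934727	2935979	FALSE
SPNCRNA.1573	II	3020526	3022271	FALSE
SPNCRNA.413	II	3150075	3150475	FALSE
SPBC13A2.04c	II	3405575	3408492	FALSE
SPBC2G2.17c	II	3466270	3467797	FALSE
SPBC887.16	II	3574869	3575250	FALSE
SPSNORNA.27	II	3654333	3654416	FALSE
SPNCRNA.1660	II	4049029	4049473	FALSE
SPBC1347.11	II	4081869	4083198	FALSE
SPNCRNA.1670	II	4109027	4109600	FALSE
SPNCRNA.577	II	4255755	4259164	FALSE
SPNCRNA.451	III	49802	50142	FALSE
SPCC757.13	III	77080	79816	FALSE
SPNCRNA.1126	III	289992	293300	FALSE
SPNCRNA.1137	III	394357	396657	FALSE
SPCC1183.12	III	604366;604857	604805;604961	FALSE
SPNCRNA.1160	III	815167	816476	FALSE
SPCPB16A4.06c	III	956012;957195	957014;957627	FALSE
SPCC550.07	III	1196729	1199999	FALSE
SPCC550.10	III	1204315	1206695	FALSE
SPCC338.18	III	1340628	1341847	FALSE
SPCC1281.04	III	1386524	1387961	FALSE
SPCC188.12	III	1504862;1505062	1504999;1506851	FALSE
SPNCRNA.51	III	1514062	1514343	FALSE
SPCC584.13	III	1516197	1518230	FALSE
SPNCRNA.1205	III	1559743	1561240	FALSE
SPCC417.02	III	1669944	1671551	FALSE
SPNCRNA.1215	III	1671883	1674238	FALSE
SPCC417.06c	III	1677093;1678329;1678828	1678286;1678778;1679436	FALSE
SPCC417.10	III	1694169	1697592	FALSE
SPCC1450.07c	III	1736500;1738213	1737778;1738318	FALSE
SPCC1442.01	III	1765913	1768971	FALSE
SPCC1223.09	III	1857150	1858621	FALSE
SPNCRNA.1236	III	1859963	1860577	FALSE
SPCC74.04	III	1935474	1938754	FALSE
SPCC576.01c	III	2079421	2080662	FALSE
SPCC830.04c	III	2186723	2187154	FALSE
SPCC965.13	III	2310096	2314400	FALSE
SPCC70.04c	III	2352568;2353746;2353974	2353701;2353913;2354572	FALSE
SPNCRNA.519	III	2362179	2362725	FALSE
SPCC569.09	III	2413905;2414158	2414089;2414790	FALSE
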