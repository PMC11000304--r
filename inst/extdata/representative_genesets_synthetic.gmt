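Keratinization	synthetic member list for the packaged example geneset	G1185	G1639	G0913	G1998	G1090	G0401	G0321	G0383	G0188	G1503	G1528	G0142	G0868	G1160	G1193	G0308	G1362	G1272	G1427	G1462
Extracellular_matrix_organization	synthetic member list for the packaged example geneset	G1084	G1283	G1599	G0494	G1869	G0239	G0931	G0838	G1840	G1600	G1779	G1859	G0742	G1162	G0622	G1655	G1699	G1517	G0249	G0463
Xenobiotic_metabolism	synthetic member list for the packaged example geneset	G1332	G1920	G1066	G0126	G1074	G0521	G0180	G0025	G1977	G0658	G0498	G0507	G1643	G0252	G1596	G0777	G1897	G1297	G0648	G0849
Cilium_organization	synthetic member list for the packaged example geneset	G1230	G0298	G0036	G0515	G1114	G0268	G1118	G1640	G0599	G1030	G1900	G1043	G0670	G1790	G0323	G1217	G1495	G1913	G0172	G1666
Inflammatory_response	synthetic member list for the packaged example geneset	G1215	G0084	G0564	G0715	G1608	G1435	G0829	G1466	G0970	G0660	G0623	G1477	G0843	G0203	G0877	G1692	G1438	G0155	G0596	G0957
Neutrophil_mediated_immunity	synthetic member list for the packaged example geneset	G0649	G0108	G1320	G0120	G1151	G0399	G0016	G1270	G1423	G0539	G1688	G1615	G0159	G1843	G0447	G1164	G1026	G0097	G1373	G0257
Response_to_interferon_gamma	synthetic member list for the packaged example geneset	G1539	G1641	G0818	G1601	G1672	G0975	G1119	G0968	G0102	G0954	G0041	G1081	G0165	G1037	G0589	G0078	G0598	G0495	G0726	G1866
Antigen_processing_and_presentation	synthetic member list for the packaged example geneset	G0746	G1201	G0591	G0438	G0676	G0631	G1591	G0423	G0893	G1673	G1023	G0133	G1873	G0553	G1702	G0068	G1999	G0344	G0865	G1082
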