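# Evaluation counts for the twelve clan-based benchmark cases (v1).
# TRUE_k: reference clan members under suffix filter k; closure_*/foldseek_*:
# positives (P) and true positives (TP) of the transitive-closure search and
# the direct fast search under the same filters. The direct fast search
# reports an unfiltered P_0, so it also has a TP_0 column; the closure search
# output is validator-filtered and its TP counts start at suffix 1.
case	clan	true_0	true_1	true_2	closure_p0	closure_p1	closure_p2	closure_tp1	closure_tp2	foldseek_p0	foldseek_p1	foldseek_p2	foldseek_tp0	foldseek_tp1	foldseek_tp2
1	CL0524	15	14	13	840	766	269	14	13	571	444	28	14	14	13
2	CL0508	74	73	64	184	79	65	72	64	1497	78	65	72	72	64
3	CL0545	186	184	181	80357	11752	5171	183	181	54559	3752	2086	179	179	178
4	CL0395	359	342	300	1354	494	445	315	299	1826	682	399	319	317	285
5	CL0080	740	719	719	8645	794	794	613	613	459	395	395	325	320	320
6	CL0209	1308	1289	1213	40253	13391	2618	1274	1211	4449	3514	1448	1172	1166	1144
7	CL0046	2058	1978	1942	36030	9308	5783	1965	1939	1975	1920	1895	1892	1868	1866
8	CL0192	10300	9387	5568	33701	13274	6012	9209	5564	3946	3637	2226	3597	3352	2093
9	CL0021	18280	10603	10299	78555	12302	11982	10538	10236	1511	1404	1404	1363	1269	1269
10	CL0113	4589	4489	3656	8390	5386	3763	4079	3652	8728	8632	2330	2411	2411	2282
11	CL0037	1100	720	718	2329	664	661	625	624	228	228	227	222	222	221
12	CL0268	1753	1732	1210	17735	3162	1356	1417	1204	638	638	544	571	571	517
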