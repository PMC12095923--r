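# Query-level inputs of the twelve clan-based benchmark cases (v1).
# core_size: chosen minimum common-core size (minlali); q_cov_pct: core size
# over query length, integer percent; z_median: median precise score of the
# query against the TRUE_1 reference members; search_time_s: search wall time.
case	query	core_size	q_cov_pct	clan	z_median	clan_description	search_time_s
1	3sb3A	85	84	CL0524	5.8	MPT63-MPB63	64
2	3zg4A	100	78	CL0508	11.4	l,d-transpeptidase catalytic domain	19
3	2mj7A	85	60	CL0545	11.0	Clathrin (AP) and COPI appendage platform subdomain	996
4	amseA	120	63	CL0395	13.4	Tubby C-terminal domain-like	52
5	ezjrA	40	33	CL0080	5.8	Beta-tent fold	152
6	fbuzA	100	58	CL0209	9.8	Bet v 1 like	964
7	jw11A	100	34	CL0046	21.7	Thiolase-like Superfamily	676
8	mr59A	180	75	CL0192	8.7	Seven transmembrane receptors	2271
9	k0wxA	50	52	CL0021	3.9	OB-fold	2430
10	rfhrA	200	63	CL0113	12.7	GT1	619
11	lx55A	60	47	CL0037	7.4	Lysozyme	230
12	1ee6A	160	81	CL0268	12.9	Right-handed beta helix similar to that first found in pectate lyase	625
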