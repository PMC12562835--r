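locus	meioses	mutations	ref_rate_fatherson	ref_rate_pedigree
DYF387S1	1576	13	0.010	0.008
DYS19	1576	0	0.002	0.002
DYS385	1576	6	0.008	0.004
DYS389I	1576	0	0.002	0.002
DYS389II	1576	1	0.006	0.004
DYS390	1576	4	0.003	0.004
DYS391	1576	2	0.003	0.004
DYS392	1576	0	0.001	0.000
DYS393	1576	1	0.002	0.001
DYS437	1576	2	0.001	0.001
DYS438	1576	0	0.000	0.001
DYS439	1576	12	0.005	0.004
DYS448	1576	1	0.001	0.003
DYS449	1576	6	0.011	0.010
DYS456	1576	6	0.004	0.002
DYS458	1576	11	0.009	0.008
DYS460	1576	8	0.004	0.006
DYS481	1576	8	0.005	0.002
DYS518	1576	18	0.013	0.016
DYS533	1576	5	0.004	0.003
DYS570	1576	5	0.008	0.010
DYS576	1576	20	0.013	0.009
DYS627	1576	21	0.015	0.014
DYS635	1576	5	0.004	0.003
YGATAH4	1576	6	0.002	0.002
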