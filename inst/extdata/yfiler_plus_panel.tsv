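locus	copies	min_allele	max_allele
DYF387S1	2	30	44
DYS19	1	9	19
DYS385	2	7	28
DYS389I	1	9	17
DYS389II	1	24	35
DYS390	1	17	29
DYS391	1	5	16
DYS392	1	4	20
DYS393	1	7	18
DYS437	1	10	18
DYS438	1	6	16
DYS439	1	8	15
DYS448	1	15	24
DYS449	1	22	40
DYS456	1	11	23
DYS458	1	10	24
DYS460	1	7	14
DYS481	1	17	32
DYS518	1	32	49
DYS533	1	7	17
DYS570	1	10	26
DYS576	1	13	25
DYS627	1	11	27
DYS635	1	15	28
YGATAH4	1	8	13
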