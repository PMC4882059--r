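# cd177conv-schema: sites/v1
site_id	rsid	g_pos	c_pos	exon	ref_base	var_base	site_class	aa_label	prevalence	hg38_pos	db_note
g.49	rs45441892	49	9	1	G	C	SNP	A3P	23/39	43353721	NA
g.220	rs45553433	220	92	2	A	T	SNP	H31L	2/39	43353892	NA
g.242	rs45571738	242	114	2	G	A	SNP	L38L	7/39	43353914	NA
g.1991	NA	1991	381	4	C	G	PSV	P128A	39/39	43355663	NA
g.2368	rs12981714	2368	551	5	T	G	PSV	V184G	38/39	43356040	hg19 ref/var reversed (A->C V184G printed)
g.2427	rs12980412	2427	610	5	G	A	PSV	D204N	38/39	43356099	hg19 reversed
g.2431	rs12981771	2431	614	5	T	G	PSV	M205R	38/39	43356103	hg19 reversed
g.6683	rs57802244	6683	710	6	T	C	SNP	M237T	1/39	43360355	NA
g.6724	rs10425835	6724	751	6	C	A	SNP	L251I	27/39	43360396	NA
g.7492	NA	7492	782	7	G	C	PSV	G261A	39/39	43361164	hg19 C->G A261G (reversed)
g.7496	NA	7496	786	7	A	C	PSV	T262T	39/39	43361168	hg19 C->A (reversed)
g.7497	NA	7497	787	7	A	T	PSV	K263X	39/39	43361169	hg19 T->A X263K (reversed)
g.7500	rs200145410	7500	790	7	G	A	PSV	G264S	39/39	43361172	hg19 A->G S264G (reversed)
g.7501	rs200006364	7501	791	7	G	T	SNP	G264V	10/39	43361173	hg19 G->T S264I (reversed)
g.7509	rs201266439	7509	798	7	A	G	PSV	T267A	39/39	43361181	hg19 G->A A267T (reversed)
g.7968	rs17856829	7968	1022	8	G	A	SNP	A348T	15/39	43361540	NA
g.8625	rs78718189	8625	1281	9	G	A	SNP	G431R	4/39	43362297	NA
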