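locus_tag	gene	product	eop_average	sd	call_this_work	call_literature
P1_gp002	cra	cre associated function	6.6E-01	1.3E-01	NE	NE[117,118]
P1_gp003	cre	cyclization recombinase	1.2E+00	8.1E-01	NE	NE[117,118]
P1_gp004	c8	establishment of lysogeny	1.5E+00	3.9E-01	NE
P1_gp005	ref	recombination enhancement	1.3E+00	3.5E-01	NE	NE[118]
P1_gp006	mat	maturation control	2.8E-01	3.5E-03	NE	E[119]
P1_gp007	res	restriction component	1.2E+00	3.5E-02	NE	NE[120]
P1_gp008	mod	modification component	1.0E+00	3.2E-01	NE	NE[120]
P1_gp009	lxc	modulator of C1 action;	7.0E-01	4.2E-01	NE	NE[121]
P1_gp010	ulx	enhances incorporation of darB	6.4E-01	1.6E-01	NE	NE[122]
P1_gp011	darB	antirestriction	5.8E-01	2.5E-01	NE	NE[122]
P1_gp012	prt	portal	<3.4E-6		E	E[52]
P1_gp013	pro	head processing	<3.4E-6		E	E[52]
P1_gp115	lydE	putative antiholin	9.8E-01	8.8E-01	NE
P1_gp014	lydD	putative holin	1.1E+00	1.0E-01	NE
P1_gp015	lyz	lysozyme	5.0E-02	3.5E-03	E	E[123]
P1_gp016	ssb	single stranded DNA binding protein	5.7E-01	2.0E-02	NE
P1_gp017	isaA	IS1 insertion-associated gene	8.6E-01	4.7E-01	NE
P1_gp018	insB	IS1 transposition protein	5.1E-01	1.6E-01	NE
P1_gp019	insA	IS1 transposition protein	1.0E+00	2.2E-01	NE
P1_gp020	isaB	IS1 insertion-associated gene	1.4E+00	2.2E-01	NE
P1_gp021	hxr	possible repressor; homolog of Xre	1.6E+00	1.2E+00	NE	NE[122]
P1_gp022	ddrB	antirestriction	8.5E-01	1.3E-01	NE	NE[122]
P1_gp116	iddB	internal to ddrB	5.4E-01	2.6E-01	NE	NE[122]
P1_gp023	ddrA	antirestriction	9.8E-01	3.1E-01	NE	NE[122]
P1_gp024	darA	antirestriction	6.5E-01	2.9E-01	NE	NE[122]
P1_gp025	hdf	antirestriction	1.2E+00	8.4E-01	NE	NE[122]
P1_gp026	lydB	lysis determinant;prevents premature lysis	2.3E-02	2.6E-02	E	NE[123,124]
P1_gp027	lydA	holin	1.2E-01	2.4E-03	NE	NE[123,124]
P1_gp028	lydC	holin	1.1E+00	1.2E-01	NE
P1_gp029	cin	site-specific recombinase	1.4E+00	9.5E-01	NE	NE[125]
P1_gp001	Sv prime	C-terminal moiety of tail fiber gpS	5.3E-01	3.2E-01	NE	NE [126]
P1_gp030	U prime	structural protein gpUprime of tail fiber	8.6E-01	8.0E-01	NE	NE [126]
P1_gp031	U	tail fiber structure or assembly	<5.2E-5		E
P1_gp032	S	tail fiber structure or assembly	<5.2E-5		E
P1_gp033	R	tail fiber structure or assembly	<5.2E-5		E	E[127]
P1_gp034	16	baseplate or tail tube	<5.2E-5		E	E[128]
P1_gp035	bplA	putative baseplate structure, may correspond to gene 3	<2.9E-5		E
P1_gp036	pmgA	Putative morphogenetic function	<2.9E-5		E	E[73]
P1_gp037	sit	putative tape measure protein	<2.9E-5		E
P1_gp038	pmgB	Putative morphogenetic function	<2.9E-5		E	E[73]
P1_gp039	tub	tail tube	<2.9E-5		E
P1_gp040	pmgC	Putative morphogenetic function	<2.9E-5		E	E[73]
P1_gp041	simC	superimmunity	1.7E+00	6.9E-01	NE	NE[129]
P1_gp042	simB	superimmunity	3.8E+00	8.4E-01	NE	NE[129]
P1_gp043	simA	superimmunity	9.0E-01	4.9E-01	NE	NE[129]
P1_gr044	c4 RNA	acts on icd and ant mRNA	8.3E-01	9.4E-01	NE
P1_gp045	icd	reversible inhibition of cell division	6.0E-01	2.2E-01	NE	NE[130]
P1_gp046	ant1	antagonizes C1 represssion1	2.0E+00	1.1E+00	NE	NE[131]
P1_gp047	ant2	product antagonizes C1	2.3E+00	1.8E+00	NE	NE[131]
P1_gp048	ask	regulatory region of kilA gene;	1.2E+00	4.9E-01	NE
P1_gp049	kilA	product can kill host	8.6E-01	8.0E-01	NE	NE[131]
P1_gp050	repL	initiates replication at oriL	7.1E-01	3.0E-01	NE	NE[131]
P1_gp051	rlfA	possibly associated withlytic replication	1.3E+00	6.1E-02	NE
P1_gp052	rlfB	possibly associated withlytic replication	8.8E-01	3.0E-02	NE
P1_gp053	pmgF	putative morphogenetic function	1.2E+00	1.0E-02	NE	NE[73]
P1_gp054	bplB	baseplate structure	<1.2E-7		E
P1_gp055	pmgG	putative morphogenetic function	<1.2E-7		E	E[73]
P1_gp056	21	baseplate or tail tube	<1.2E-7		E	* [128]
P1_gp057	22	tail sheath	<1.2E-7		E	* [128]
P1_gp058	23	Major head protein	<1.2E-7		E	* [128]
P1_gp059	parB	active partitioning of P1 plasmidduring cell division	1.3E+00	7.6E-01	NE
P1_gp060	parA	active partitioning of P1 plasmidduring cell division	1.6E+00	1.5E+00	NE
P1_gp061	repA	initiates replication from oriR;plasmid replication	9.5E-01	6.4E-02	NE
P1_gp062	upfA		1.2E+00	8.9E-01	NE	NE[73]
P1_gp063	mlp	membrane lipoprotein precursor	2.4E-01	1.9E-01	NE
P1_gp064	ppfA	possible periplasmic function	1.3E+00	1.2E+00	NE
P1_gp065	upfB		1.3E+00	1.0E+00	NE	NE[73]
P1_gp066	upfC		1.1E+00	6.8E-01	NE	NE[73]
P1_gp067	uhr		8.6E-01	1.9E-01	NE	NE[73]
P1_gp068	hrdC	hpothetical recombinationassociated protein of RdgC family	8.7E-01	4.6E-01	NE
P1_gp069	dmt-B	DNA methlytransferases;methlysates A at GATC	1.4E+00	1.2E+00	NE	NE[132]
P1_gp070	dmt-A		1.4E+00	7.6E-03	NE
P1_gt071	trnT		9.2E-01	4.0E-01	NE
P1_gp072	plp	putative lipoprotein	1.6E+00	8.2E-01	NE
P1_gp073	upl		1.9E+00	5.9E-01	NE	NE[73]
P1_gp074	tciA	tellurite or colicin resistance or inhibition of cell division	6.5E-01	6.5E-02	NE
P1_gp075	tciB	tellurite or colicin resistance or inhibition of cell division	9.9E-01	1.0E-01	NE
P1_gp076	tciC	tellurite or colicin resistance or inhibition of cell division	1.3E+00	4.4E-01	NE
P1_gt117	trnI		1.4E+00	7.9E-01	NE
P1_gp077	ban	dnaB homolog	1.2E+00	4.8E-01	NE	NE[133]
P1_gp078	dbn	downstream of ban	1.3E+00	1.3E-01	NE	NE[73]
P1_gp079	5	baseplate	<2.1E-6		E	* [128]
P1_gp080	6	tail length	8.3E-03	1.3E-03	E	* [128]
P1_gp081	24	baseplate or tail stability	4.9E-03	5.0E-03	E	* [128]
P1_gp082	7	tail stability	<8.2E-6		E	* [128]
P1_gp083	25	tail stability	1.1E-01	6.6E-02	NE	* [128]
P1_gp084	26	baseplate;	1.2E-01	1.5E-01	NE	* [128]
P1_gp085	pmgL	putative morphogenetic function	1.3E+00	9.4E-01	NE	NE[73]
P1_gp086	pmgM	putative morphogenetic function	3.8E-01	2.1E-01	NE	NE[73]
P1_gp087	pmgN	putative morphogenetic function	1.4E-02	1.5E-03	E	NE[73]
P1_gp088	pmgO	putative morphogenetic function	1.1E+00	8.7E-01	NE	NE[73]
P1_gp089	pmgP	putative morphogenetic function	7.2E-01	7.3E-02	NE	NE[73]
P1_gp090	ppp	protein phosphatase	1.2E+00	8.0E-02	NE	NE[73]
P1_gp091	pmgQ	putative morphogenetic function	1.4E+00	7.5E-01	NE	NE[73]
P1_gp092	pmgR	putative morphogenetic function	9.4E-01	3.0E-01	NE	E[73]
P1_gp093	pmgS	putative morphogenetic function	1.2E+00	3.2E-01	NE	NE[73]
P1_gp094	pap	acid phosphatase	7.7E-01	2.3E-01	NE	NE[73]
P1_gp095	pmgT	putative morphogenetic function	9.8E-01	9.7E-01	NE	NE[73]
P1_gp096	pmgU	putative morphogenetic function	2.1E-01	6.4E-02	NE	NE[73]
P1_gp097	pmgV	putative morphogenetic function	1.9E+00	2.0E+00	NE	NE[73]
P1_gp098	upfM	unknown protein function			NT	NE[73]
P1_gp099	upfN	unknown protein function	8.3E-01	2.4E-01	NE	NE[73]
P1_gp100	upfO	unknown protein function	9.5E-01	6.4E-01	NE	NE[73]
P1_gp101	hot	DNA replication	1.2E+00	1.6E+00	NE
P1_gp102	lxr	LexA-regulated functions	7.9E-01	7.7E-01	NE
P1_gp103	humD	DNA repair	5.4E-01	3.3E-01	NE
P1_gp104	phd	anti-toxin of P1 toxin-antitoxin system	5.5E-01	7.1E-02	NE
P1_gp105	doc	toxin of P1 toxin-antitoxin system	3.6E-01	1.2E-02	NE
P1_gp106	pdcA	unknown protein function			NT	NE[73]
P1_gp107	pdcB	unknown function	6.8E-01	2.6E-01	NE	NE[73]
P1_gp108	lpa	late promoter activator	<1.2E-7		E	* [134]
P1_gp109	pacA	DNA packaging	<1.2E-7		E	* [135]
P1_gp110	pacB	DNA packaging	<1.2E-7		E	* [135]
P1_gp111	c1	lytic repressor	1.4E+00	1.3E+00	NE
P1_gp112	coi	C1 inactivator	7.4E-01	8.4E-01	NE	NE[136]
P1_gp113	imcB	immunity function	8.2E-01	7.3E-01	NE
P1_gp114	imcA	immunity function			NT
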