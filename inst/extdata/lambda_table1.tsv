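locus_tag	gene	product	eop_average	sd	call_this_work	call_literature
lambdap01	nu1	DNA packaging protein	5.5E-06	2.1E-06	E	E [91]
lambdap02	A	TerL	1.3E-06	4.7E-07	E	E [92,93]
lambdap03	W	gpW family protein	3.0E-05	1.4E-05	E	E [93,94]
lambdap04	B	portal	2.5E-05	2.1E-05	E	E [92,93]
lambdap05	C	S49 family peptidase/capsid component; Viral protease	<2.0E-7		E	E [93,95]
lambdap06	nu3	scaffolding protein	<2.0E-7		E	E [93,96]
lambdap07	D	head decoration protein	6.8E-06	2.4E-07	E	E [93,97]
lambdap08	E	major capsid protein	<6.4E-6		E	E [93,97]
lambdap09	Fi	DNA packaging protein FI	2.0E-05	0.0E+00	E	E [93,98]
lambdap10	Fii	head-tail joining protein	<2.0E-7		E	E [94]
lambdap11	Z	tail protein	2.5E-05	7.1E-06	E	E [55]
lambdap12	U	tail protein	3.5E-05	2.1E-05	E	E [55]
lambdap13	V	tail protein	1.7E-05	1.9E-05	E	E [55]
lambdap14	G	minor tail protein G	<6.4E-6		E	E [99]
lambdap15	T	tail assembly protein T	1.2E-05	1.2E-05	E	E [99]
lambdap16	H	tail tape measure protein	1.0E-06	9.4E-07	E	E [99]
lambdap17	M	tail protein	<2.0E-7		E	E [99]
lambdap18	L	minor tail protein L	<2.0E-7		E	E [99]
lambdap19	K	tail protein	8.7E-05	1.2E-04	E	E [99]
lambdap20	I	tail component	2.6E-05	2.7E-05	E	E [100]
lambdap21	J	host specificity protein J	1.1E-05	1.2E-05	E	E [92]
lambdap26	lom	Outer membrane beta-barrel protein Lom	8.8E-01	5.3E-01	NE	NE [17]
lambdap27	stf	protail fiber N-terminal domain containing protein	3.0E+00	2.8E+00	NE	NE [62]
lambdap90	orf206b	hypothetical protein	4.3E+00	1.1E+00	NE	NE [62]
lambdap28	tfa	tail fiber protein	6.3E+00	5.3E+00	NE	NE [62]
lambdap29	orf-194	tail fiber assembly protein	3.3E+00	1.1E+00	NE	NE [62]
lambdap80	ea47		5.5E+00	6.4E+00	NE	NE [17]
lambdap81	ea31		1.2E+00	1.1E+00	NE	NE [17]
lambdap82	ea59	ATP-dependent endonuclease	1.3E+01	1.7E+01	NE	NE [17]
lambdap33	int	tyrosine-type recombinase/integrase	2.8E+00	3.2E+00	NE	NE [55]
lambdap34	xis	excisionase	1.6E+00	1.1E+00	NE	NE [55]
lambdap35					NT
lambdap36	ea8.5		1.4E+00	1.3E+00	NE	NE [17]
lambdap83	ea22	ead/Ea22-like family protein	2.2E+00	2.3E+00	NE	NE [17]
lambdap37	orf61	hypothetical protein	9.7E-01	8.1E-01	NE	NE [17]
lambdap38	orf63	DUF1382 family protein	1.3E+00	3.8E-01	NE	NE [17]
lambdap39	orf60a	DUF1317 domin-containing protein	2.4E+00	2.0E+00	NE	NE [17]
lambdap41	exo	YqaJ viral recombinase family protein	6.9E-01	4.4E-01	NE	NE [17]
lambdap84	bet	recombination protein Bet	2.1E+00	2.5E+00	NE	NE [17,101]
lambdap42	gam	host-nuclease inhibitor protein Gam	1.4E+00	1.3E+00	NE	NE [17,101]
lambdap85	kil	host cell division inhibitory peptide Kil	1.0E+00	0.0E+00	NE	NE [102]
lambdap86	cIII	protease FtsH-inhibitory lysogeny factor CIII	1.1E+00	3.1E-01	NE	NE [103,104]
lambdap45	ea10	DUF2528 family protein	1.7E+00	4.7E-01	NE	NE [17]
lambdap46	ral	Restriction inhibitor protein ral	1.1E+00	3.2E-01	NE	NE [60,61]
lambdap47	orf28	hypothetical protein	1.3E+00	4.7E-01	NE	NE [17]
lambdap48	sieB	Superinfection exclusion protein B	1.5E+00	7.1E-01	NE	NE [105]
lambdap49	N	antitermination protein N	1.8E-04	1.2E-04	E	E [106,107]
lambdap53	rexB	exclusion protein	1.4E+00	1.3E+00	NE	NE [17,105]
lambdap87	rexA	exclusion protein	3.8E+00	4.0E+00	NE	NE [17,105]
lambdap88	cI	lysogenic repressor	5.3E+00	6.6E+00	NE	NE [103,108,109]
lambdap57	cro	lytic repressor	<7.5E-6		E	E [110]
	cII				NT	NE [103,108,109]
lambdap89	O	replication protein	<7.5E-6		E	E [111,112]
lambdap61	P	DNA replication protein	<7.5E-6		E	E [111,112]
lambdap62	ren	protein ren	1.20E-02	7.7E-06	E	NE [113]
lambdap63	ninB	recombination protein NinB	3.00E-05	5.4E-04	E	NE [17,65]
lambdap64	ninC	phosphoadenosine phosphosulfate reductase family protein	clearing on E-1		E	NE [17,65]
	ninD				NT	NE [17,65]
	ninE				NT	NE [17,65]
lambdap67	ninF		4.00E-05	4.0E-06	E	NE [17,65]
lambdap68	ninG	recombination protein NinG	8.0E-06	1.1E-04	E	NE
	ninH				NT	NE [17,65,113]
lambdap70	ninI	serine/threonine phosphatase	4.0E-06	5.8E-06	E	NE [17,65]
lambdap71	Q	antitermination protein	1.6E-05	6.1E-06	E	E [65]
lambdap73	orf-64	hypothetical protein	1.2E-02	9.1E-02	NE
lambdap74	S	holin/anti-holin	1.0E-05	4.6E-05	E	E [114]
lambdap92	S'	holin/anti-holin	1.0E-05	1.7E-04	E	E [114]
lambdap75	R	endolysin	6.0E-02	5.1E-02	NE	E [115]
lambdap76	Rz	I-spanin	5.0E-04	1.5E-01	E	E [116]
	Rz1				NT	E [116]
lambdap77	bor	serum resistance lipoprotein Bor	7.9E-01	3.0E-01	NE	NE [17]
lambdap78	-	putative envelope protein	1.9E+00	1.3E+00	NE	NE [17]
lambdap79	-	hypothetical protein	3.0E-04	1.1E-04	E	NE [17]
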