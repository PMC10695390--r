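locus_tag	gene	product	eop_average	sd	call_this_work	call_literature
lambdap62	ren	protein ren	1.20E-02	1.7E+00	NE	NE [113]
lambdap63	ninB	recombination protein NinB	3.00E-01	9.1E-01	NE	NE [17,65]
lambdap64	ninC		1.00E+00	1.5E+00	NE	NE [17,65]
	ninD					NE [17,65]
	ninE					NE [17,65]
lambdap67	ninF		0.03	1.4E+00	NE	NE [17,65]
lambdap68	ninG	recombination protein NinG	0.2	2.1E-01	NE	NE
	ninH					NE [17,65,113]
lambdap70	ninI	serine/threonine phosphatase	1	1.5E+00	NE	NE [17,65]
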