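unit_name	rank	locus_tag
PL	1	lambdap49
PL	2	lambdap48
PL	3	lambdap47
PL	4	lambdap46
PL	5	lambdap45
PL	6	lambdap86
PL	7	lambdap85
PL	8	lambdap42
PL	9	lambdap84
PL	10	lambdap41
PL	11	lambdap39
PL	12	lambdap38
PL	13	lambdap37
PL	14	lambdap83
PL	15	lambdap36
PL	16	lambdap35
PL	17	lambdap34
PL	18	lambdap33
PL	19	lambdap82
PL	20	lambdap81
PL	21	lambdap80
PR	1	lambdap57
PR	2	cII
PR	3	lambdap89
PR	4	lambdap61
PR	5	lambdap62
PR	6	lambdap63
PR	7	lambdap64
PR	8	ninD
PR	9	ninE
PR	10	lambdap67
PR	11	lambdap68
PR	12	ninH
PR	13	lambdap70
PR	14	lambdap71
PR_prime	1	lambdap73
PR_prime	2	lambdap74
PR_prime	3	lambdap92
PR_prime	4	lambdap75
PR_prime	5	lambdap76
PR_prime	6	Rz1
PR_prime	7	lambdap77
PR_prime	8	lambdap78
PR_prime	9	lambdap79
PR_prime	10	lambdap01
PR_prime	11	lambdap02
PR_prime	12	lambdap03
PR_prime	13	lambdap04
PR_prime	14	lambdap05
PR_prime	15	lambdap06
PR_prime	16	lambdap07
PR_prime	17	lambdap08
PR_prime	18	lambdap09
PR_prime	19	lambdap10
PR_prime	20	lambdap11
PR_prime	21	lambdap12
PR_prime	22	lambdap13
PR_prime	23	lambdap14
PR_prime	24	lambdap15
PR_prime	25	lambdap16
PR_prime	26	lambdap17
PR_prime	27	lambdap18
PR_prime	28	lambdap19
PR_prime	29	lambdap20
PR_prime	30	lambdap21
PR_prime	31	lambdap26
PR_prime	32	lambdap27
PR_prime	33	lambdap90
PR_prime	34	lambdap28
PR_prime	35	lambdap29
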