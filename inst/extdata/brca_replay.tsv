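# Recorded kinase-binding predictions for BRCA1/BRCA2 variant queries.
# Wild-type (state=wt) and mutant (state=mut) predictions are recorded in the
# context of each variant query, as the per-variant predictor output was
# matched against the corresponding wild-type run. site = catalogued site
# position, or the altered residue for sites created by the substitution.
# bound=FALSE marks a prediction recorded as retaining a score that fell
# below the reliability threshold in the mutant.
protein	variant	state	site	kinase	bound
BRCA1	p.K309T	wt	308	STK6	TRUE
BRCA1	p.K309T	mut	309	ATM	TRUE
BRCA1	p.S632N	wt	632	CDK2	TRUE
BRCA1	p.P633T	wt	632	CDK2	TRUE
BRCA1	p.P633T	mut	633	CDK2	TRUE
BRCA1	p.P633S	wt	632	CDK2	TRUE
BRCA1	p.P633S	mut	633	CDK2	TRUE
BRCA1	p.P633S	mut	633	MAPK14	TRUE
BRCA1	p.P633S	mut	633	MAPK13	TRUE
BRCA1	p.P633S	mut	633	MAPK11	TRUE
BRCA1	p.P633S	mut	633	MAPK10	TRUE
BRCA1	p.P633S	mut	633	MAPK9	TRUE
BRCA1	p.P633S	mut	633	MAPK8	TRUE
BRCA1	p.S1143F	wt	1143	ATM	TRUE
BRCA1	p.Q1144H	wt	1143	ATM	TRUE
BRCA1	p.Q1281P	wt	1280	ATM	TRUE
BRCA1	p.S1542C	wt	1542	CSNK2A2	TRUE
BRCA1	p.S1542C	wt	1542	CK2A1	TRUE
BRCA2	p.S196I	wt	193	TGFBR2	TRUE
BRCA2	p.S196I	wt	193	ACVR2B	TRUE
BRCA2	p.T207A	wt	207	NEK2	TRUE
BRCA2	p.P3292L	wt	3291	CDK2	TRUE
BRCA2	p.P3292L	wt	3291	MAPK11	TRUE
BRCA2	p.P3292L	wt	3291	MAPK13	TRUE
BRCA2	p.P3292L	wt	3291	MAPK14	TRUE
BRCA1	p.S403F	wt	403	CK2A1	TRUE
BRCA1	p.S403F	wt	403	CSNK2A1	TRUE
BRCA1	p.N417S	mut	417	CK2A1	TRUE
BRCA1	p.N417S	mut	417	CSNK2A1	TRUE
BRCA1	p.D420Y	mut	420	IGF1R	TRUE
BRCA1	p.D420Y	mut	420	INSR	TRUE
BRCA1	p.S454N	wt	454	CK2A1	TRUE
BRCA1	p.S454N	wt	454	CSNK2A1	TRUE
BRCA1	p.N609S	wt	615	RPS6KB1	TRUE
BRCA1	p.N609S	mut	615	RPS6KB1	TRUE
BRCA1	p.N609S	mut	609	PRKDC	TRUE
BRCA1	p.R612G	wt	615	RPS6KB1	TRUE
BRCA1	p.D749Y	wt	753	CK2A1	TRUE
BRCA1	p.D749Y	wt	753	CSNK2A1	TRUE
BRCA1	p.G1201S	wt	1211	CK2A1	TRUE
BRCA1	p.G1201S	wt	1211	CSNK2A1	TRUE
BRCA1	p.G1201S	mut	1211	CK2A1	TRUE
BRCA1	p.G1201S	mut	1211	CSNK2A1	TRUE
BRCA1	p.G1201S	mut	1201	NEK2	TRUE
BRCA1	p.G1201S	mut	1201	PRKCD	TRUE
BRCA1	p.G1201S	mut	1201	PRKCI	TRUE
BRCA1	p.G1201S	mut	1201	PRKCQ	TRUE
BRCA1	p.G1201S	mut	1201	PRKCZ	TRUE
BRCA1	p.G1201S	mut	1201	PRKCA	TRUE
BRCA1	p.G1201S	mut	1201	PRKCG	TRUE
BRCA1	p.E1214K	wt	1211	CK2A1	TRUE
BRCA1	p.E1214K	wt	1211	CSNK2A1	TRUE
BRCA1	p.E1214K	wt	1212	CK2A1	TRUE
BRCA1	p.E1214K	wt	1212	CSNK2A1	TRUE
BRCA1	p.E1214K	mut	1211	CK2A1	FALSE
BRCA1	p.E1214K	mut	1211	CSNK2A1	FALSE
BRCA1	p.S1217P	wt	1218	CK2A1	TRUE
BRCA1	p.S1217P	wt	1218	CSNK2A1	TRUE
BRCA1	p.S1218C	wt	1218	CSNK2A2	TRUE
BRCA1	p.S1218C	wt	1218	CK2A1	TRUE
BRCA1	p.R1507T	mut	1507	TGFBR2	TRUE
BRCA1	p.R1507T	mut	1507	ACVR2B	TRUE
BRCA1	p.T1550I	wt	1550	NEK2	TRUE
BRCA1	p.S1577P	wt	1577	CSNK2A2	TRUE
BRCA1	p.S1577P	wt	1577	CK2A1	TRUE
BRCA1	p.A1584S	wt	1577	CSNK2A2	TRUE
BRCA1	p.A1584S	wt	1577	CK2A1	TRUE
BRCA1	p.A1584S	mut	1577	CSNK2A2	TRUE
BRCA1	p.A1584S	mut	1577	CK2A1	TRUE
BRCA1	p.A1584S	mut	1584	CDK2	TRUE
BRCA1	p.A1584S	mut	1584	MAPK8	TRUE
BRCA1	p.A1584S	mut	1584	MAPK10	TRUE
BRCA1	p.A1584S	mut	1584	MAPK9	TRUE
BRCA1	p.A1584S	mut	1584	MAPK14	TRUE
BRCA1	p.A1584S	mut	1584	MAPK11	TRUE
BRCA1	p.A1584S	mut	1584	MAPK13	TRUE
BRCA1	p.F1695L	wt	1700	TGFBR2	TRUE
BRCA1	p.F1695L	wt	1700	ACVR2B	TRUE
BRCA1	p.F1695L	wt	1700	PRKCD	TRUE
BRCA1	p.F1695L	wt	1700	PRKC	TRUE
BRCA1	p.F1695L	wt	1700	PRKCQ	TRUE
BRCA1	p.F1695L	wt	1700	PRKCZ	TRUE
BRCA1	p.F1695L	wt	1700	PRKCA	TRUE
BRCA1	p.F1695L	wt	1700	PRKCG	TRUE
BRCA1	p.F1695L	wt	1700	MST2	TRUE
BRCA1	p.R1699L	wt	1700	PRKCD	TRUE
BRCA1	p.R1699L	wt	1700	PRKC	TRUE
BRCA1	p.R1699L	wt	1700	PRKCQ	TRUE
BRCA1	p.R1699L	wt	1700	PRKCZ	TRUE
BRCA1	p.R1699L	wt	1700	PRKCA	TRUE
BRCA1	p.R1699L	wt	1700	PRKCG	TRUE
BRCA1	p.R1699L	wt	1700	MST2	TRUE
BRCA1	p.R1699W	wt	1700	PRKCD	TRUE
BRCA1	p.R1699W	wt	1700	PRKC	TRUE
BRCA1	p.R1699W	wt	1700	PRKCQ	TRUE
BRCA1	p.R1699W	wt	1700	PRKCZ	TRUE
BRCA1	p.R1699W	wt	1700	PRKCA	TRUE
BRCA1	p.R1699W	wt	1700	PRKCG	TRUE
BRCA1	p.R1699W	wt	1700	MST2	TRUE
BRCA1	p.T1720A	wt	1720	ATM	TRUE
BRCA2	p.D1923A	wt	1926	CSNK2A2	TRUE
BRCA2	p.D1923A	wt	1926	CK2A1	TRUE
BRCA2	p.D1923A	mut	1926	CSNK2A2	FALSE
BRCA2	p.D1923A	mut	1926	CK2A1	FALSE
BRCA2	p.D1923V	wt	1926	CSNK2A2	TRUE
BRCA2	p.D1923V	wt	1926	CK2A1	TRUE
BRCA2	p.D1923V	mut	1926	CSNK2A2	FALSE
BRCA2	p.D1923V	mut	1926	CK2A1	FALSE
BRCA2	p.P3194Q	wt	3193	CDK2	TRUE
BRCA2	p.P3194Q	mut	3193	ATM	TRUE
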