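# In-vivo phosphosites of BRCA1/BRCA2 named in the packaged recorded-prediction
# tables. characterized = kinase binding and biological role demonstrated
# experimentally; FALSE = identified by high-throughput phosphoproteomics only.
# known_kinases = recorded wild-type binders (semicolon-joined; may be empty).
protein_id	position	acceptor	characterized	known_kinases	note
BRCA1	308	S	TRUE	STK6	Aurora-A/STK6 binding regulates G2-M transition
BRCA1	632	S	TRUE	CDK2	phosphorylation regulates BRCA1-dependent transcription
BRCA1	1143	S	TRUE	ATM	localization of BRCA1 to alkylation-damage foci
BRCA1	1280	S	TRUE	ATM	localization of BRCA1 to alkylation-damage foci
BRCA1	1542	S	TRUE	CSNK2A2;CK2A1	response to ionizing-radiation double-strand breaks
BRCA1	403	S	FALSE	CK2A1;CSNK2A1	cell-cycle regulation screen
BRCA1	454	S	FALSE	CK2A1;CSNK2A1	DNA damage response after ionizing radiation
BRCA1	615	S	FALSE	RPS6KB1	Akt-RSK-S6 signalling network
BRCA1	753	S	FALSE	CK2A1;CSNK2A1	mitotic phosphosite occupancy
BRCA1	1211	S	FALSE	CK2A1;CSNK2A1	
BRCA1	1212	S	FALSE	CK2A1;CSNK2A1	
BRCA1	1217	S	FALSE		phosphorylated in vivo; recorded kinase not available
BRCA1	1218	S	FALSE	CSNK2A2;CK2A1	mitotic phosphosite occupancy
BRCA1	1550	T	FALSE	NEK2	rapamycin-sensitive phosphosite
BRCA1	1577	S	FALSE	CSNK2A2;CK2A1	mitotic phosphosite occupancy
BRCA1	1700	T	FALSE	TGFBR2;ACVR2B;PRKCD;PRKC;PRKCQ;PRKCZ;PRKCA;PRKCG;MST2	DNA damage response
BRCA1	1720	T	FALSE	ATM	DNA damage response
BRCA2	193	S	TRUE	TGFBR2;ACVR2B	regulates BRCA2 interaction with P/CAF
BRCA2	207	T	TRUE	NEK2	regulates BRCA2 interaction with P/CAF
BRCA2	3291	S	TRUE	CDK2;MAPK11;MAPK13;MAPK14	CDK phosphorylation gates RAD51 binding
BRCA2	1926	S	FALSE	CSNK2A2;CK2A1	mass-spectrometry screen
BRCA2	3193	T	FALSE	CDK2	mass-spectrometry screen
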