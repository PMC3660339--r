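# BIC missense VUS recorded as altering (or rescuing) phosphorylation motifs
# of BRCA1/BRCA2. frequency = number of times reported in BIC.
protein	mutation	cdna	snp_id	exon	frequency	source
BRCA1	p.K309T	c.926A>C	rs80356877	11A	1	characterized
BRCA1	p.S632N	c.1895G>A	rs80356983	11B	1	characterized
BRCA1	p.P633T	c.1897C>A	NA	11B	1	characterized
BRCA1	p.P633S	c.1897C>T	rs80356902	11B	1	characterized
BRCA1	p.S1143F	c.3428C>T	rs80357434	11D	1	characterized
BRCA1	p.Q1144H	c.3432G>T	rs80356922	11D	1	characterized
BRCA1	p.Q1281P	c.3842A>C	rs80357483	11D	2	characterized
BRCA1	p.S1542C	c.4625C>G	rs41293457	15	2	characterized
BRCA2	p.S196I	c.587G>T	rs80358818	7	1	characterized
BRCA2	p.T207A	c.619A>G	rs80358858	7	2	characterized
BRCA2	p.P3292L	c.9865C>T	rs56121817	27	7	characterized
BRCA1	p.S403F	c.1208C>T	rs80356934	11A	1	uncharacterized
BRCA1	p.N417S	c.1250A>G	rs80357113	11A	2	uncharacterized
BRCA1	p.D420Y	c.1258G>T	rs80357488	11A	3	uncharacterized
BRCA1	p.S454N	c.1361G>A	rs80357181	11A	1	uncharacterized
BRCA1	p.N609S	c.1826A>G	rs80357326	11A	1	uncharacterized
BRCA1	p.R612G	c.1834A>G	rs80357245	11A	1	uncharacterized
BRCA1	p.D749Y	c.2245G>T	rs80357114	11B	1	uncharacterized
BRCA1	p.G1201S	c.3601G>A	rs55725337	11D	3	uncharacterized
BRCA1	p.E1214K	c.3655G>A	NA	11D	9	uncharacterized
BRCA1	p.S1217P	c.3649T>C	NA	11D	1	uncharacterized
BRCA1	p.S1218C	c.3652A>T	rs80356894	11D	2	uncharacterized
BRCA1	p.R1507T	c.4520G>C	rs80357470	15	2	uncharacterized
BRCA1	p.T1550I	c.4649C>T	rs80357076	15	3	uncharacterized
BRCA1	p.S1577P	c.4729T>C	rs80356909	16	1	uncharacterized
BRCA1	p.A1584S	c.4750G>T	rs80357070	16	1	uncharacterized
BRCA1	p.F1695L	c.5085T>A	rs80357837	18	1	uncharacterized
BRCA1	p.R1699L	c.5096G>T	rs41293459	18	1	uncharacterized
BRCA1	p.R1699W	c.5095C>T	rs55770810	18	13	uncharacterized
BRCA1	p.T1720A	c.5158A>G	rs56195342	19	15	uncharacterized
BRCA2	p.D1923A	c.5768A>C	rs45491005	11E	9	uncharacterized
BRCA2	p.D1923V	c.5768A>T	rs45491005	11E	1	uncharacterized
BRCA2	p.P3194Q	c.9581C>A	rs28897760	26	6	uncharacterized
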