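# Recorded conservation annotation per variant: harmonized label and A-GVGD
# class as published. The per-caller columns (sift_call, polyphen_call) are
# RECONSTRUCTED canonically from the harmonized label (damaging ->
# damaging + probably_damaging; likely_damaging -> damaging + benign;
# benign -> tolerated + benign); only the harmonized label and class are
# recorded values.
variant	sift_call	polyphen_call	harmonized	agvgd_class
p.K309T	damaging	probably_damaging	damaging	C0
p.S632N	damaging	benign	likely_damaging	C0
p.P633T	damaging	benign	likely_damaging	C0
p.P633S	damaging	benign	likely_damaging	C0
p.S1143F	damaging	benign	likely_damaging	C0
p.Q1144H	damaging	benign	likely_damaging	C0
p.Q1281P	damaging	probably_damaging	damaging	C0
p.S1542C	damaging	benign	likely_damaging	C0
p.S196I	damaging	probably_damaging	damaging	C65
p.T207A	damaging	probably_damaging	damaging	C55
p.P3292L	damaging	probably_damaging	damaging	C0
p.S403F	tolerated	benign	benign	C0
p.N417S	tolerated	benign	benign	C0
p.D420Y	damaging	probably_damaging	damaging	C15
p.S454N	tolerated	benign	benign	C0
p.N609S	damaging	benign	likely_damaging	C0
p.R612G	damaging	benign	likely_damaging	C0
p.D749Y	damaging	probably_damaging	damaging	C0
p.G1201S	tolerated	benign	benign	C0
p.E1214K	damaging	probably_damaging	damaging	C0
p.S1217P	damaging	probably_damaging	damaging	C65
p.S1218C	damaging	probably_damaging	damaging	C25
p.R1507T	damaging	benign	likely_damaging	C0
p.T1550I	tolerated	benign	benign	C0
p.S1577P	damaging	benign	likely_damaging	C0
p.A1584S	tolerated	benign	benign	C0
p.F1695L	damaging	benign	likely_damaging	C0
p.R1699L	damaging	probably_damaging	damaging	C65
p.R1699W	damaging	probably_damaging	damaging	C65
p.T1720A	damaging	benign	likely_damaging	C0
p.D1923A	damaging	probably_damaging	damaging	C0
p.D1923V	damaging	probably_damaging	damaging	C0
p.P3194Q	damaging	probably_damaging	damaging	C0
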