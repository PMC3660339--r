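# Denominators of the analysis: missense VUS retrieved from BIC per gene and
# the subset located in or within 10 residues of a catalogued phosphosite.
protein	n_retrieved	n_analyzed
BRCA1	591	191
BRCA2	883	43
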