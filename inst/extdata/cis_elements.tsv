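name	pattern	category
TATA-box	TATAWAW	core_promoter
CAAT-box	CCAAT	core_promoter
CArG	CCWWWWWWGG	protein_binding
MBS	CAACTG	protein_binding
CCAAT-box	CAACGG	protein_binding
ABRE	ACGTGKC	hormone_response
CGTCA-motif	CGTCA	hormone_response
TGACG-motif	TGACG	hormone_response
TCA-element	CCATCTTTTT	hormone_response
Skn-1	GTCAT	tissue_specific
GCN4-motif	TGAGTCA	tissue_specific
CAT-box	GCCACT	tissue_specific
CCGTCC-box	CCGTCC	tissue_specific
G-box	CACGTG	light_response
Sp1	GGGCGG	light_response
TCT-motif	TCTTAC	light_response
GT1-motif	GGTTAA	light_response
ARE	AAACCA	stress_response
LTR	CCGAAA	stress_response
HSE	AAAAAATTTC	stress_response
GC-motif	CCCCCG	stress_response
TC-rich	ATTTTCTTCA	stress_response
AAGAA-motif	GAAAGAA	stress_response
circadian	CAANNNNATC	circadian
MSA-like	YCYAACGGYY	cell_cycle
W-box	TTGACC	other
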