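# Curated representative subset of the PAINS (pan-assay interference)
# alert families (A/B/C), version targan-2026.09. One SMARTS<TAB>name
# per line. This is a hand-curated subset of recognisable interference
# motifs, not the full published catalog.
[OX2H]c1ccccc1[OX2H]	catechol
O=C1C=CC(=O)C=C1	para_quinone
O=C1C(=O)C=CC=C1	ortho_quinone
O=C1CSC(=S)N1	rhodanine
O=C1NC(=S)SC1=[CX3]	ene_rhodanine
[OX2H]c1ccccc1[CX3]=[NX2][NX3]	hydroxyphenyl_hydrazone
cN=Nc	aromatic_azo
[SX2H]c	thiophenol
O=C1NC(=O)NC(=O)C1=[CX3]	alkylidene_barbiturate
[CX3]=[CX3][CX3](=O)[CX3]=[CX3]	cross_conjugated_dienone
[NX3][CX3]=[CX3][CX3]=O	beta_enamine_ketone
[OX2H]c1ccccc1[CX3]=O	salicylaldehyde_like
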