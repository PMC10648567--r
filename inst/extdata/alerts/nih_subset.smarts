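# Curated representative subset of the NIH reactive-functionality
# alerts, version targan-2026.09.
[CX3](=O)[NX3][NX3]	acyl_hydrazide
[F,Cl,Br,I]c1ccccn1	2_halo_pyridine
O=C1[CX4][CX4]N1	beta_lactam
O=C1C=CC(=O)N1	maleimide
[CX3]=[NX2][OX2H]	oxime
[#6][NX2]=O	nitroso
[C-]#[N+]	isocyanide
S(=O)(=O)[F,Cl,Br,I]	sulfonyl_halide
[CX3](=O)O[CX3](=O)	anhydride
[CX3](=O)[SX2]	thioester
[NX4+]	quaternary_nitrogen
[CX3](=[OX1])[OX2][NX3]	activated_ester
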