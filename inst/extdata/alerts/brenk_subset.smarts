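# Curated representative subset of the Brenk reactive/undesirable-moiety
# alerts, version targan-2026.09. Focused on reactive and assay-hostile
# functionality; lead-likeness flags (e.g. long aliphatic chains) are
# deliberately not included.
[$([NX3](=O)=O),$([NX3+](=O)[O-])]	nitro_group
[CX3H1](=O)[#6]	aldehyde
[CX3](=O)[F,Cl,Br,I]	acyl_halide
[CX4][Br,I]	alkyl_heavy_halide
C1[O,N,S]C1	three_membered_heterocycle
[SX2H]	thiol
[NX2]=[NX2]	azo_or_azide
[NX2]=C=[O,S]	isocyanate_isothiocyanate
[NX3;!$(N=O)][NX3]	hydrazine
[OX2][OX2]	peroxide
[CX3]=[CX3][CX3](=O)[#6]	vinyl_ketone_michael_acceptor
[CX3]=[CX3]C#N	acrylonitrile_michael_acceptor
[SX2][SX2]	disulfide
[P]	phosphorus
[CX3]=[NX2][!#8]	acyclic_imine
[CX2]#[CX2]	alkyne
[S;X3](=O)[OX2H,OX1-]	sulfinic_acid
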