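# Curated representative subset of ZINC-style undesirable-moiety
# alerts, version targan-2026.09.
[Si]	silicon
[B]	boron
[Se]	selenium
C(Cl)(Cl)Cl	trichloromethyl
[CX3]=[CX3][OX2][CX4]	acyclic_enol_ether
[NX3][CX3](=S)[NX3]	thiourea
C=CC=CC=CC=C	extended_polyene
OCCOCCOCC	polyether_chain
[NX2]=C=[NX2]	carbodiimide
[CX4]([OX2][#6])([OX2][#6])[#1,#6]	acyclic_acetal
[F,Cl,Br,I][CX4][F,Cl,Br,I]	geminal_dihalide
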