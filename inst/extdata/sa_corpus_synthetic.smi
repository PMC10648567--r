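CC(=O)Oc1ccccc1C(=O)O aspirin
CC(=O)Nc1ccc(O)cc1 paracetamol
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
COc1ccc2cc(ccc2c1)C(C)C(=O)O naproxen
CCOC(=O)c1ccc(N)cc1 benzocaine
CCN(CC)CC(=O)Nc1c(C)cccc1C lidocaine
CCN(CC)CCOC(=O)c1ccc(N)cc1 procaine
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol
CC(C)NCC(O)COc1cccc2ccccc12 propranolol
COCCc1ccc(OCC(O)CNC(C)C)cc1 metoprolol
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21 diazepam
OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O ciprofloxacin
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21 chlorpromazine
CN(C)CCCN1c2ccccc2CCc2ccccc21 imipramine
CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1 fluoxetine
CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21 sertraline
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O warfarin
O=c1ccc2ccccc2o1 coumarin
CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O testosterone
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O estradiol
CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C cholesterol
CCO ethanol
OCC(O)CO glycerol
OCC1OC(O)C(O)C(O)C1O glucose
OC(=O)CC(O)(C(=O)O)CC(=O)O citric_acid
NC(N)=O urea
CN1CCCC1c1cccnc1 nicotine
NCCc1c[nH]cn1 histamine
NCCc1c[nH]c2ccc(O)cc12 serotonin
NCCc1ccc(O)c(O)c1 dopamine
CNCC(O)c1ccc(O)c(O)c1 adrenaline
NC(Cc1ccc(O)cc1)C(=O)O tyrosine
NC(Cc1c[nH]c2ccccc12)C(=O)O tryptophan
NC(Cc1ccccc1)C(=O)O phenylalanine
CC(C)CC(N)C(=O)O leucine
OCC(O)C1OC(=O)C(O)=C1O ascorbic_acid
CC(C)C1CCC(C)CC1O menthol
CC(=C)C1CCC(C)=CC1 limonene
CC1=CCC2CC1C2(C)C alpha_pinene
CC1(C)C2CCC1(C)C(=O)C2 camphor
COc1cc(C=O)ccc1O vanillin
COc1cc(CC=C)ccc1O eugenol
Cc1ccc(C(C)C)c(O)c1 thymol
Cc1ccc(C(C)C)cc1O carvacrol
Oc1cccc(O)c1 resorcinol
CCCCCc1cc(O)cc(O)c1 olivetol
CCCCCc1cc2c(c(O)c1)C1C=C(C)CCC1C(C)(C)O2 thc
c1ccccc1 benzene
Cc1ccccc1 toluene
Oc1ccccc1 phenol
Nc1ccccc1 aniline
OC(=O)c1ccccc1 benzoic_acid
COc1ccccc1 anisole
c1ccncc1 pyridine
c1cncnc1 pyrimidine
c1c[nH]cn1 imidazole
c1ccc2[nH]ccc2c1 indole
c1ccoc1 furan
c1ccsc1 thiophene
C1CCNCC1 piperidine
C1CNCCN1 piperazine
C1COCCN1 morpholine
C1CCNC1 pyrrolidine
C1CCCCC1 cyclohexane
C1CCCC1 cyclopentane
c1ccc2ccccc2c1 naphthalene
c1ccc(-c2ccccc2)cc1 biphenyl
CN(C)C(=N)NC(N)=N metformin
CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12 chloroquine
CC(CS)C(=O)N1CCCC1C(=O)O captopril
Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1 celecoxib
CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1 ketoprofen
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl diclofenac
Oc1ccc2ccccc2c1 naphthol
COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1 indomethacin
COc1ccc2[nH]cc(CCNC(C)=O)c2c1 melatonin
OC(=O)C=Cc1ccc(O)c(O)c1 caffeic_acid
O=CC=Cc1ccccc1 cinnamaldehyde
NCC1(CC(=O)O)CCCCC1 gabapentin
CC(C)CC(CN)CC(=O)O pregabalin
CCCC(CCC)C(=O)O valproate
NC1C2CC3CC1CC(C2)C3 amantadine
CC12CC3CC(C)(C1)CC(N)(C3)C2 memantine
COc1cc2c(cc1OC)C(=O)C(CC1CCN(Cc3ccccc3)CC1)C2 donepezil
CCN(C)C(=O)Oc1cccc(C(C)N(C)C)c1 rivastigmine
Nc1c2c(nc3ccccc13)CCCC2 tacrine
CCCCCc1cc(O)c(C2C=C(C)CCC2C(=C)C)c(O)c1 cannabidiol
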