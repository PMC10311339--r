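name	smiles
aspirin	CC(=O)Oc1ccccc1C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
naproxen	COc1ccc2cc(ccc2c1)C(C)C(=O)O
benzene	c1ccccc1
toluene	Cc1ccccc1
phenol	Oc1ccccc1
pyridine	c1ccncc1
pyrazole	c1cc[nH]n1
imidazole	c1c[nH]cn1
nicotine	CN1CCCC1c1cccnc1
benzamide	NC(=O)c1ccccc1
salicylic_acid	OC(=O)c1ccccc1O
atenolol	CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
sulfanilamide	Nc1ccc(cc1)S(=O)(=O)N
coumarin	O=c1ccc2ccccc2o1
indole	c1ccc2[nH]ccc2c1
quinoline	c1ccc2ncccc2c1
piperidine	C1CCNCC1
diazepam	CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1
warfarin	CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
metoprolol	COCCc1ccc(OCC(O)CNC(C)C)cc1
propranolol	CC(C)NCC(O)COc1cccc2ccccc12
lidocaine	CCN(CC)CC(=O)Nc1c(C)cccc1C
procaine	CCN(CC)CCOC(=O)c1ccc(N)cc1
ketoprofen	CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1
diclofenac	OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl
fluoxetine	CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1
sertraline	CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12
citalopram	CN(C)CCCC1(OCc2cc(ccc12)C#N)c1ccc(F)cc1
haloperidol	OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1
chlorpromazine	CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc12
imipramine	CN(C)CCCN1c2ccccc2CCc2ccccc12
amitriptyline	CN(C)CCC=C1c2ccccc2CCc2ccccc12
metronidazole	Cc1ncc(n1CCO)[N+](=O)[O-]
trimethoprim	COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC
sulfamethoxazole	Cc1cc(no1)NS(=O)(=O)c1ccc(N)cc1
ciprofloxacin	OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O
isoniazid	NNC(=O)c1ccncc1
pyrazinamide	NC(=O)c1cnccn1
theophylline	Cn1c2c(c(=O)n(C)c1=O)[nH]cn2
allopurinol	O=c1[nH]cnc2[nH]ncc12
cimetidine	CC1=C(CSCCNC(=NC)NC#N)N=CN1
ranitidine	CNC(=CC1=CC=C(O1)CN(C)C)[N+](=O)[O-]
omeprazole	COc1ccc2[nH]c(nc2c1)S(=O)Cc1ncc(C)c(OC)c1C
amoxicillin_core	CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O
gabapentin	NCC1(CC(=O)O)CCCCC1
tramadol	CN(C)CC1CCCCC1(O)c1cccc(OC)c1
levodopa	NC(Cc1ccc(O)c(O)c1)C(=O)O
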