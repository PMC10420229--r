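name,smiles,tags
Ethylbenzene,CCc1ccccc1,alkylbenzene
Propylbenzene,CCCc1ccccc1,alkylbenzene
Butylbenzene,CCCCc1ccccc1,alkylbenzene
1-Phenylethanone,CC(=O)c1ccccc1,aryl ketone
1-Phenylpropan-1-one,CCC(=O)c1ccccc1,aryl ketone
1-Phenylbutan-1-one,CCCC(=O)c1ccccc1,aryl ketone
1-Phenylpentan-1-one,CCCCC(=O)c1ccccc1,aryl ketone
1-Phenylheptan-1-one,CCCCCCC(=O)c1ccccc1,aryl ketone
Furan,c1ccoc1,heterocycle
2-Nitroaniline,Nc1ccccc1[N+](=O)[O-],nitroaniline
"2,3-Benzofuran",c1ccc2occc2c1,heterocycle
Diphenylmethanone,O=C(c1ccccc1)c1ccccc1,aryl ketone
Benzamide,NC(=O)c1ccccc1,amide
4-Chloroaniline,Nc1ccc(Cl)cc1,aniline
"2,3-Dimethylphenol",Oc1c(C)c(C)ccc1,phenol
Naphtalen-2-ol,Oc1ccc2ccccc2c1,phenol
4-Aminobenzamide,NC(=O)c1ccc(N)cc1,amide
3-Methylphenol,Cc1cccc(O)c1,phenol
"2,4-Dimethylphenol",Oc1c(C)cc(C)cc1,phenol
Naphthalene,c1ccc2ccccc2c1,arene
Pyrimidine,c1cncnc1,azine
Benzaldehyde,O=Cc1ccccc1,aldehyde
3-Chloroaniline,Nc1cccc(Cl)c1,aniline
Pyrrole,c1cc[nH]c1,azole
3-Nitroaniline,Nc1cccc([N+](=O)[O-])c1,nitroaniline
4-Chlorophenol,Oc1ccc(Cl)cc1,phenol
Phenol,Oc1ccccc1,phenol
Methylbenzoate,COC(=O)c1ccccc1,ester
Bromobenzene,Brc1ccccc1,halobenzene
"1,4-Xylene",Cc1ccc(C)cc1,alkylbenzene
"Benzene-1,3-diol",Oc1cccc(O)c1,phenol
2-Methylaniline,Cc1ccccc1N,aniline
Aniline,Nc1ccccc1,aniline
Nitrobenzene,O=[N+]([O-])c1ccccc1,nitroarene
Chlorobenzene,Clc1ccccc1,halobenzene
N-4-chlorophenylacetamide,CC(=O)Nc1ccc(Cl)cc1,amide
N-Phenylacetamide,CC(=O)Nc1ccccc1,amide
4-Nitroaniline,Nc1ccc([N+](=O)[O-])cc1,nitroaniline
Anisole,COc1ccccc1,ether
Benzonitrile,N#Cc1ccccc1,nitrile
1-Ethyl-4-nitrobenzene,CCc1ccc([N+](=O)[O-])cc1,nitroarene
Benzyl benzoate,O=C(OCc1ccccc1)c1ccccc1,ester
Caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,xanthine
Corticosterone,CC12CCC(=O)C=C1CCC1C2C(O)CC2(C)C1CCC2C(=O)CO,hormone
Cortisone,CC12CCC(=O)C=C1CCC1C2C(=O)CC2(C)C1CCC2(O)C(=O)CO,hormone
beta-Estradiol,CC12CCC3c4ccc(O)cc4CCC3C1CCC2O,hormone
Estriol,CC12CCC3c4ccc(O)cc4CCC3C1CC(O)C2O,hormone
Cortisol,CC12CCC(=O)C=C1CCC1C2C(O)CC2(C)C1CCC2(O)C(=O)CO,hormone
Hydroquinone,Oc1ccc(O)cc1,phenol
Quinoline,c1ccc2ncccc2c1,azine
Atrazine,CCNc1nc(Cl)nc(NC(C)C)n1,pesticide
Diuron,CN(C)C(=O)Nc1ccc(Cl)c(Cl)c1,pesticide
Isoproturon,CC(C)c1ccc(NC(=O)N(C)C)cc1,pesticide
Linuron,CON(C)C(=O)Nc1ccc(Cl)c(Cl)c1,pesticide
Metobromuron,CON(C)C(=O)Nc1ccc(Br)cc1,pesticide
Monuron,CN(C)C(=O)Nc1ccc(Cl)cc1,pesticide
Metoxuron,CN(C)C(=O)Nc1ccc(OC)c(Cl)c1,pesticide
Phenylurea,NC(=O)Nc1ccccc1,pesticide
Propazine,CC(C)Nc1nc(Cl)nc(NC(C)C)n1,pesticide
Fluometuron,CN(C)C(=O)Nc1cccc(C(F)(F)F)c1,pesticide
"N,N-Diethyl-4-nitroaniline",CCN(CC)c1ccc([N+](=O)[O-])cc1,nitroaniline
1-Methoxy-4-nitrobenzene,COc1ccc([N+](=O)[O-])cc1,nitroarene
1-Methoxy-2-nitrobenzene,COc1ccccc1[N+](=O)[O-],nitroarene
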