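name,smiles,synonyms
ethyl hexanoate,CCCCCC(=O)OCC,ethyl caproate;hexanoic acid ethyl ester
methyl salicylate,COC(=O)c1ccccc1O,methyl 2-hydroxybenzoate;wintergreen oil
octanal,CCCCCCCC=O,caprylic aldehyde;octyl aldehyde
undecane,CCCCCCCCCCC,n-undecane
linalool,CC(C)=CCCC(C)(O)C=C,"1,6-octadien-3-ol, 3,7-dimethyl-"
limonene,CC1=CCC(CC1)C(=C)C,d-limonene
nonanal,CCCCCCCCC=O,nonyl aldehyde;pelargonaldehyde
3-octanone,CCCCCC(=O)CC,ethyl amyl ketone
mesitylene,Cc1cc(C)cc(C)c1,"benzene, 1,3,5-trimethyl-"
p-cymene,Cc1ccc(cc1)C(C)C,1-methyl-4-isopropylbenzene
tetradecane,CCCCCCCCCCCCCC,n-tetradecane
decane,CCCCCCCCCC,n-decane
"1-heptene, 2,4-dimethyl-",CC(CC(=C)C)CCC,"2,4-dimethyl-1-heptene"
1-octen-3-ol,CCCCCC(O)C=C,matsutake alcohol
benzaldehyde,O=Cc1ccccc1,benzenecarboxaldehyde
2-phenylethanol,OCCc1ccccc1,phenylethyl alcohol
hexanal,CCCCCC=O,caproaldehyde
alpha-pinene,CC1=CCC2CC1C2(C)C,"bicyclo[3.1.1]hept-2-ene, 2,6,6-trimethyl-"
beta-ocimene,C=CC(C)=CCC=C(C)C,"1,3,6-octatriene, 3,7-dimethyl-"
eucalyptol,CC12CCC(CC1)C(C)(C)O2,"1,8-cineole"
nonane,CCCCCCCCC,n-nonane
toluene,Cc1ccccc1,methylbenzene
ethylbenzene,CCc1ccccc1,phenylethane
styrene,C=Cc1ccccc1,vinylbenzene
acetophenone,CC(=O)c1ccccc1,"ethanone, 1-phenyl-"
geraniol,CC(C)=CCCC(C)=CCO,"2,6-octadien-1-ol, 3,7-dimethyl-, (E)-"
citronellal,CC(CCC=C(C)C)CC=O,"6-octenal, 3,7-dimethyl-"
camphor,CC1(C)C2CCC1(C)C(=O)C2,2-bornanone
methyl benzoate,COC(=O)c1ccccc1,niobe oil
benzyl alcohol,OCc1ccccc1,phenylmethanol
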