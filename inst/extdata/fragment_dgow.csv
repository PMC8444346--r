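# Fragment octanol-water partitioning table (curated experimental logP).
# Keys are OpenBabel canonical SMILES of the hydrogen-capped fragment.
# Fragments missing from this table fall back to Wildman-Crippen atom
# contributions (J. Chem. Inf. Comput. Sci. 1999, 39, 868-873).
smiles,name,logp
C,methane,1.09
CC,ethane,1.81
CCC,propane,2.36
CCCC,butane,2.89
CC(C)C,isobutane,2.76
CCCCC,pentane,3.39
CC(C)(C)C,neopentane,3.11
CCC(C)C,2-methylbutane,3.21
CCCCCC,hexane,3.90
CCCCCCC,heptane,4.66
CCCCCCCC,octane,5.18
CCCCCCCCC,nonane,5.65
CCCCCCCCCC,decane,5.98
C=C,ethene,1.13
CC=C,propene,1.77
CCC=C,1-butene,2.40
C#C,ethyne,0.37
C1CCCCC1,cyclohexane,3.44
C1CCCC1,cyclopentane,3.00
C1CCC=CC1,cyclohexene,2.86
c1ccccc1,benzene,2.13
Cc1ccccc1,toluene,2.73
CCc1ccccc1,ethylbenzene,3.15
C=Cc1ccccc1,styrene,2.95
c1ccc2c(c1)cccc2,naphthalene,3.30
c1ccc(cc1)c1ccccc1,biphenyl,4.01
Oc1ccccc1,phenol,1.46
Nc1ccccc1,aniline,0.90
COc1ccccc1,anisole,2.11
O=Cc1ccccc1,benzaldehyde,1.48
CC(=O)c1ccccc1,acetophenone,1.58
OC(=O)c1ccccc1,benzoic-acid,1.87
[O-][N+](=O)c1ccccc1,nitrobenzene,1.85
Fc1ccccc1,fluorobenzene,2.27
Clc1ccccc1,chlorobenzene,2.84
Brc1ccccc1,bromobenzene,2.99
c1cccnc1,pyridine,0.65
c1ccc[nH]1,pyrrole,0.75
c1ccco1,furan,1.34
c1cccs1,thiophene,1.81
c1ccncn1,pyrimidine,-0.44
c1ncc[nH]1,imidazole,-0.05
CO,methanol,-0.77
CCO,ethanol,-0.31
CCCO,1-propanol,0.25
CC(O)C,2-propanol,0.05
CCCCO,1-butanol,0.88
CCCCCO,1-pentanol,1.51
CC(O)(C)C,tert-butanol,0.35
OCCO,ethylene-glycol,-1.36
OCC(O)C,propylene-glycol,-0.92
OCC(CO)O,glycerol,-1.76
COC,dimethyl-ether,0.10
CCOCC,diethyl-ether,0.89
C1CCCO1,tetrahydrofuran,0.46
O1CCOCC1,dioxane,-0.27
C=O,formaldehyde,0.35
CC=O,acetaldehyde,-0.17
CCC=O,propanal,0.59
CC(=O)C,acetone,-0.24
CCC(=O)C,butanone,0.29
OC=O,formic-acid,-0.54
CC(=O)O,acetic-acid,-0.17
CCC(=O)O,propanoic-acid,0.33
COC=O,methyl-formate,0.03
COC(=O)C,methyl-acetate,0.18
CCOC(=O)C,ethyl-acetate,0.73
NC=O,formamide,-1.51
CC(=O)N,acetamide,-1.26
NC(=O)N,urea,-2.11
CN,methylamine,-0.57
CCN,ethylamine,-0.13
CCCN,propylamine,0.48
CNC,dimethylamine,-0.38
CCNCC,diethylamine,0.58
CN(C)C,trimethylamine,0.16
CCN(CC)CC,triethylamine,1.45
CC#N,acetonitrile,-0.34
[O-][N+](=O)C,nitromethane,-0.35
ClC(Cl)Cl,chloroform,1.97
ClCCl,dichloromethane,1.25
CCl,chloromethane,0.91
CCCl,chloroethane,1.43
CBr,bromomethane,1.19
CS,methanethiol,0.78
CCS,ethanethiol,1.27
CSC,dimethyl-sulfide,0.92
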