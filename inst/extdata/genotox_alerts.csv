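name,smarts,note
aromatic nitro,"[c][NX3+](=[OX1])[O-]",nitroarene; reduced in vivo to reactive nitroso/hydroxylamine species
aromatic amine,"[NX3;H2,H1;!$(NC=O);!$(NN)][c]",primary/secondary arylamine; excludes anilides and hydrazines
N-nitroso,"[NX3][NX2]=[OX1]",N-nitrosamine / N-nitrosamide
epoxide,"[OX2;r3]",three-membered oxirane ring
aziridine,"[NX3;r3]",three-membered nitrogen ring
aromatic azo,"[c][NX2]=[NX2][c]",azoarene; cleaved to aromatic amines
hydrazine,"[NX3;!$(NC=O)][NX3;!$(NC=O)]",hydrazine / hydrazide nitrogen-nitrogen single bond
activated alkyl halide benzylic,"[Cl,Br,I][CX4H2][c]",benzylic halide
activated alkyl halide allylic,"[Cl,Br,I][CX4H2][CX3]=[CX3]",allylic halide
alpha-halo carbonyl,"[Cl,Br,I][CX4][CX3]=[OX1]",halide alpha to a carbonyl
alpha-beta unsaturated carbonyl,"[CX3]=[CX3][CX3]=[OX1]",Michael acceptor
aromatic N-oxide,"[O-][n+]",pyridine-N-oxide-like
alkyl sulfonate ester,"[#6][SX4](=[OX1])(=[OX1])[OX2][#6]",sulfonic acid ester; direct alkylator
alkyl sulfate diester,"[#6][OX2][SX4](=[OX1])(=[OX1])[OX2][#6]",sulfuric acid diester; direct alkylator
alkyl phosphonate ester,"[#6][PX4](=[OX1])([OX2][#6])[OX2][#6]",phosphonic acid ester with a carbon-phosphorus bond
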