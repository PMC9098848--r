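name,category
MaxAbsEStateIndex,T
MaxEStateIndex,T
MinAbsEStateIndex,T
MinEStateIndex,T
qed,DF
SPS,T
MolWt,P
HeavyAtomMolWt,P
ExactMolWt,P
NumValenceElectrons,E
NumRadicalElectrons,E
MaxPartialCharge,E
MinPartialCharge,E
MaxAbsPartialCharge,E
MinAbsPartialCharge,E
FpDensityMorgan1,DF
FpDensityMorgan2,DF
FpDensityMorgan3,DF
BalabanJ,T
BertzCT,C
Chi0,P
Chi0n,P
Chi0v,P
Chi1,P
Chi1n,P
Chi1v,P
Chi2n,P
Chi2v,P
Chi3n,P
Chi3v,P
Chi4n,P
Chi4v,P
HallKierAlpha,P
Kappa1,P
Kappa2,P
Kappa3,P
LabuteASA,P
PEOE_VSA1,P
PEOE_VSA10,P
PEOE_VSA11,P
PEOE_VSA12,P
PEOE_VSA13,P
PEOE_VSA14,P
PEOE_VSA2,P
PEOE_VSA3,P
PEOE_VSA4,P
PEOE_VSA5,P
PEOE_VSA6,P
PEOE_VSA7,P
PEOE_VSA8,P
PEOE_VSA9,P
SMR_VSA1,P
SMR_VSA10,P
SMR_VSA2,P
SMR_VSA3,P
SMR_VSA4,P
SMR_VSA5,P
SMR_VSA6,P
SMR_VSA7,P
SMR_VSA8,P
SMR_VSA9,P
SlogP_VSA1,P
SlogP_VSA10,P
SlogP_VSA11,P
SlogP_VSA12,P
SlogP_VSA2,P
SlogP_VSA3,P
SlogP_VSA4,P
SlogP_VSA5,P
SlogP_VSA6,P
SlogP_VSA7,P
SlogP_VSA8,P
SlogP_VSA9,P
TPSA,P
EState_VSA1,T
EState_VSA10,T
EState_VSA11,T
EState_VSA2,T
EState_VSA3,T
EState_VSA4,T
EState_VSA5,T
EState_VSA6,T
EState_VSA7,T
EState_VSA8,T
EState_VSA9,T
VSA_EState1,T
VSA_EState10,T
VSA_EState2,T
VSA_EState3,T
VSA_EState4,T
VSA_EState5,T
VSA_EState6,T
VSA_EState7,T
VSA_EState8,T
VSA_EState9,T
FractionCSP3,C
HeavyAtomCount,C
NHOHCount,C
NOCount,C
NumAliphaticCarbocycles,C
NumAliphaticHeterocycles,C
NumAliphaticRings,C
NumAromaticCarbocycles,C
NumAromaticHeterocycles,C
NumAromaticRings,C
NumHAcceptors,C
NumHDonors,C
NumHeteroatoms,C
NumRotatableBonds,C
NumSaturatedCarbocycles,C
NumSaturatedHeterocycles,C
NumSaturatedRings,C
RingCount,C
MolLogP,P
MolMR,P
fr_Al_COO,C
fr_Al_OH,C
fr_Al_OH_noTert,C
fr_ArN,C
fr_Ar_COO,C
fr_Ar_N,C
fr_Ar_NH,C
fr_Ar_OH,C
fr_COO,C
fr_COO2,C
fr_C_O,C
fr_C_O_noCOO,C
fr_C_S,C
fr_HOCCN,C
fr_Imine,C
fr_NH0,C
fr_NH1,C
fr_NH2,C
fr_N_O,C
fr_Ndealkylation1,C
fr_Ndealkylation2,C
fr_Nhpyrrole,C
fr_SH,C
fr_aldehyde,C
fr_alkyl_carbamate,C
fr_alkyl_halide,C
fr_allylic_oxid,C
fr_amide,C
fr_amidine,C
fr_aniline,C
fr_aryl_methyl,C
fr_azide,C
fr_azo,C
fr_barbitur,C
fr_benzene,C
fr_benzodiazepine,C
fr_bicyclic,C
fr_diazo,C
fr_dihydropyridine,C
fr_epoxide,C
fr_ester,C
fr_ether,C
fr_furan,C
fr_guanido,C
fr_halogen,C
fr_hdrzine,C
fr_hdrzone,C
fr_imidazole,C
fr_imide,C
fr_isocyan,C
fr_isothiocyan,C
fr_ketone,C
fr_ketone_Topliss,C
fr_lactam,C
fr_lactone,C
fr_methoxy,C
fr_morpholine,C
fr_nitrile,C
fr_nitro,C
fr_nitro_arom,C
fr_nitro_arom_nonortho,C
fr_nitroso,C
fr_oxazole,C
fr_oxime,C
fr_para_hydroxylation,C
fr_phenol,C
fr_phenol_noOrthoHbond,C
fr_phos_acid,C
fr_phos_ester,C
fr_piperdine,C
fr_piperzine,C
fr_priamide,C
fr_prisulfonamd,C
fr_pyridine,C
fr_quatN,C
fr_sulfide,C
fr_sulfonamd,C
fr_sulfone,C
fr_term_acetylene,C
fr_tetrazole,C
fr_thiazole,C
fr_thiocyan,C
fr_thiophene,C
fr_unbrch_alkane,C
fr_urea,C
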