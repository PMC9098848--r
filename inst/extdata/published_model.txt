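# Fisher classification functions for anti-DPPH activity of phenolic
# compounds: the published 16-descriptor model (two-group stepwise
# discriminant analysis, positive = IC50/EC50 <= 300 uM).
# Coefficients are reported to the printed precision; the descriptor
# toolkit version used for fitting was not published.
format: fisher_model/1
backend: rdkit
backend_version: unknown
prior_positive: 0.5
prior_negative: 0.5
const_positive: -88.150
const_negative: -112.807
coefficients:
qed	47.691	62.455
MinAbsPartialCharge	19.218	-52.885
FpDensityMorgan2	-67.637	-112.116
FpDensityMorgan3	14.345	30.362
FpDensityMorgan1	151.179	200.918
MinAbsEStateIndex	23.987	43.389
Kappa2	0.353	2.401
PEOE_VSA6	0.416	0.820
SMR_VSA4	-0.458	-0.078
SlogP_VSA5	-0.481	-0.614
VSA_EState9	2.353	1.871
NOCount	-9.660	-5.499
fr_C_O_noCOO	-10.962	-14.661
fr_allylic_oxid	-2.070	-3.966
fr_aryl_methyl	2.719	3.980
fr_ester	-7.376	-0.809
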