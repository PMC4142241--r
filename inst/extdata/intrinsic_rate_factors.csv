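# Sequence-dependence factors for intrinsic backbone amide exchange
# (H -> D, protein dissolved in D2O), log10 units relative to
# poly-DL-alanine. Compiled from the reference tables of Bai, Milne,
# Mayne & Englander (1993) Proteins 17:75-86 as distributed in the
# Englander laboratory reference spreadsheets (with the His values of
# Connelly et al. 1993). Swap this file to use a different calibration.
#
# lamA/lamB: effect of the residue's side chain on its OWN amide
#            (acid- / base-catalysed pathways)
# rhoA/rhoB: effect on the FOLLOWING residue's amide
# Ionizable side chains have _prot (protonated) and _deprot rows that are
# blended at run time by the Henderson-Hasselbalch fraction at the given
# pD. NT = N-terminal ammonium (affects residue 2, rho only);
# CT = C-terminal carboxyl (affects the last residue, lam only).
# Water-catalysed exchange uses the base (lamB/rhoB) factors.
key,lamA,rhoA,lamB,rhoB
A,0.00,0.00,0.00,0.00
R,-0.59,-0.32,0.08,0.22
N,-0.58,-0.13,0.49,0.32
C,-0.54,-0.46,0.62,0.55
G,-0.22,0.22,0.27,0.17
Q,-0.47,-0.27,0.06,0.20
I,-0.91,-0.59,-0.73,-0.23
L,-0.57,-0.13,-0.58,-0.21
K,-0.56,-0.29,-0.04,0.12
M,-0.64,-0.28,-0.01,0.11
F,-0.52,-0.43,-0.24,0.06
P,0.00,-0.19,0.00,-0.24
S,-0.44,-0.39,0.37,0.30
T,-0.79,-0.47,-0.07,0.20
W,-0.40,-0.44,-0.41,-0.11
Y,-0.41,-0.37,-0.27,0.05
V,-0.74,-0.30,-0.70,-0.14
D_prot,-0.90,-0.12,0.69,0.60
D_deprot,0.90,0.58,0.10,-0.18
E_prot,-0.60,-0.27,0.24,0.39
E_deprot,-0.90,0.31,-0.11,-0.15
H_prot,-0.80,-0.51,0.80,0.83
H_deprot,0.00,0.00,-0.10,0.14
NT,NA,-1.32,NA,1.62
CT_prot,0.96,NA,-1.80,NA
CT_deprot,0.05,NA,0.00,NA
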