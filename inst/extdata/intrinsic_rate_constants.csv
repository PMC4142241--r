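# Reference rate constants and physical constants for intrinsic amide
# exchange of poly-DL-alanine (H -> D in D2O at 293 K), after Bai et al.
# (1993). lg_* are log10 values; ka/kb in 1/(M min), kw in 1/min.
# Activation energies in kcal/mol (Arrhenius correction from T_ref).
# Side-chain pKa values are the D2O values used to blend the protonated
# and deprotonated factor rows; pKD is the D2O autoionization constant.
name,value
lg_ka,1.62
lg_kb,10.18
lg_kw,-1.5
pKD,15.05
Ea_acid,14.0
Ea_base,17.0
Ea_water,19.0
T_ref,293.0
pKa_asp,4.48
pKa_glu,4.93
pKa_his,7.42
pKa_cterm,4.00
R_cal,1.987
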