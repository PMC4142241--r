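# Van der Waals radii (Angstrom) by element, used for numerical
# solvent-accessible surface area. Values follow the widely used Bondi
# (1964) compilation (J Phys Chem 68:441) with the common protein-force-
# field value for hydrogen.
element,radius
H,1.20
C,1.70
N,1.55
O,1.52
S,1.80
P,1.80
SE,1.90
F,1.47
CL,1.75
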