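# Coherent neutron scattering lengths (Sears, Neutron News 3 (1992) 26),
# atomic numbers and standard atomic/isotopic masses.
# label: element symbol for the natural-abundance mixture, or mass number +
#        symbol for a specific isotope ("2H" has the alias "D").
# b_coh_fm: bound coherent scattering length in fm.
# Z: atomic number (X-ray branch uses f1 = Z).
# mass_amu: atomic mass in g/mol, used for formula-unit number densities.
label	b_coh_fm	Z	mass_amu
H	-3.739	1	1.008
1H	-3.7406	1	1.0078
2H	6.671	1	2.0141
C	6.6460	6	12.011
13C	6.19	6	13.0034
N	9.36	7	14.007
15N	6.44	7	15.0001
O	5.803	8	15.999
F	5.654	9	18.998
Na	3.63	11	22.990
Mg	5.375	12	24.305
Si	4.1491	14	28.085
P	5.13	15	30.974
S	2.847	16	32.06
Cl	9.5770	17	35.45
K	3.67	19	39.098
Ca	4.70	20	40.078
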