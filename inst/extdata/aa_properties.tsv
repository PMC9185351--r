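# pepVote amino-acid physicochemical property table, version 1
# Scales: hydrophobicity = Kyte-Doolittle; hydrophilicity = Hopp-Woods;
# charge = net side-chain charge at pH 7 (His +0.1); flexibility =
# Bhaskaran-Ponnuswamy average flexibility; solvent_accessible_surface_area =
# Tien et al. theoretical maximum ASA (A^2); polarity = Grantham;
# polarizability = Charton-Charton; irreplaceability = inverse Dayhoff
# relative mutability (100/m); rigidity = Zimmerman bulkiness (steric proxy).
# Values are raw; the package standardizes each scale to mean 0, population SD 1.
residue	hydrophobicity	hydrophilicity	charge	flexibility	irreplaceability	solvent_accessible_surface_area	polarity	polarizability	rigidity
A	1.8	-0.5	0	0.360	1.00	129	8.1	0.046	11.50
C	2.5	-1.0	0	0.350	5.00	167	5.5	0.128	13.46
D	-3.5	3.0	-1	0.510	0.94	193	13.0	0.105	11.68
E	-3.5	3.0	-1	0.500	0.98	223	12.3	0.151	13.57
F	2.8	-2.5	0	0.310	2.44	240	5.2	0.290	19.80
G	-0.4	0.0	0	0.540	2.04	104	9.0	0.000	3.40
H	-3.2	-0.5	0.1	0.320	1.52	224	10.4	0.230	13.69
I	4.5	-1.8	0	0.460	1.04	197	5.2	0.186	21.40
K	-3.9	3.0	1	0.470	1.79	236	11.3	0.219	15.71
L	3.8	-1.8	0	0.370	2.50	201	4.9	0.186	21.40
M	1.9	-1.3	0	0.300	1.06	224	5.7	0.221	16.25
N	-3.5	0.2	0	0.460	0.75	195	11.6	0.134	12.82
P	-1.6	0.0	0	0.510	1.79	159	8.0	0.131	17.43
Q	-3.5	0.2	0	0.490	1.08	225	10.5	0.180	14.45
R	-4.5	3.0	1	0.530	1.54	274	10.5	0.291	14.28
S	-0.8	0.3	0	0.510	0.83	155	9.2	0.062	9.47
T	-0.7	-0.4	0	0.440	1.03	172	8.6	0.108	15.77
V	4.2	-1.5	0	0.390	1.35	174	5.9	0.140	21.57
W	-0.9	-3.4	0	0.310	5.56	285	5.4	0.409	21.67
Y	-1.3	-2.3	0	0.420	2.44	263	6.2	0.298	18.03
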