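residue	dg_mid	pos_sigma
A	0.11	0.5
C	-0.13	0.5
D	3.49	0.5
E	2.68	0.5
F	-0.32	0.5
G	0.74	0.5
H	2.06	0.5
I	-0.60	0.5
K	2.71	0.5
L	-0.55	0.5
M	-0.10	0.5
N	2.05	0.5
P	2.23	0.5
Q	2.36	0.5
R	2.58	0.5
S	0.84	0.5
T	0.52	0.5
V	-0.31	0.5
W	0.30	0.5
Y	0.68	0.5
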