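residue	log_enrichment
A	0.127
C	-0.175
D	0.072
E	0.325
F	0.380
G	0.110
H	0.105
I	0.432
K	-0.700
L	-0.036
M	-0.570
N	-0.021
P	-0.036
Q	-0.376
R	0.168
S	-0.537
T	0.126
V	0.134
W	0.719
Y	-0.012
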