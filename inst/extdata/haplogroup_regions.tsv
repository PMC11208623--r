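prefix	region
A	Americas
B	Americas
C	Americas
D	Americas
X	Americas
H	Europe
V	Europe
J	Europe
T	Europe
U	Europe
K	Europe
I	Europe
W	Europe
R	Europe
L	Africa
M	Asia
N	Asia
G	Asia
F	Asia
Y	Asia
Z	Asia
E	Asia
Q	Oceania
P	Oceania
S	Oceania
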