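aa	group
A	G01
G	G01
V	G02
L	G02
I	G02
F	G03
Y	G04
W	G05
C	G06
M	G07
P	G08
S	G09
T	G09
N	G10
Q	G10
D	G11
E	G11
K	G12
R	G12
H	G13
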