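label	unit_mass	role
A	100	coding
B	105	coding
C	110	coding
D	115	coding
E	120	coding
F	125	coding
G	130	coding
H	135	coding
I	140	coding
J	145	coding
K	150	coding
L	155	coding
M	160	coding
N	165	coding
O	170	coding
*	175	spacer
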