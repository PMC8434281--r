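residue	X1	X2	X3
A	3	3	1
C	0	0	0
D	1	1	0
E	6	6	8
F	0	1	1
G	0	0	7
H	1	4	3
I	1	3	0
K	5	2	4
L	2	0	2
M	0	0	0
N	2	3	2
P	8	3	3
Q	4	0	0
R	6	3	1
S	0	3	2
T	3	3	3
V	1	4	3
W	1	1	0
Y	0	4	4
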