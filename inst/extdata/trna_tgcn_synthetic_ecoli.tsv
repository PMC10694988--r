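amino_acid	anticodon	tgcn
A	TGC	3
A	GGC	2
R	ACG	4
R	CCG	1
R	TCT	1
R	CCT	1
N	GTT	4
D	GTC	3
C	GCA	1
Q	TTG	2
Q	CTG	2
E	TTC	4
G	GCC	4
G	TCC	1
G	CCC	1
H	GTG	1
I	GAT	3
I	CAT	1
M	CAT	6
L	TAA	1
L	CAA	1
L	GAG	1
L	TAG	1
L	CAG	4
K	TTT	6
F	GAA	2
P	GGG	1
P	TGG	1
P	CGG	1
S	GGA	2
S	TGA	1
S	CGA	1
S	GCT	1
T	GGT	2
T	TGT	1
T	CGT	2
W	CCA	1
Y	GTA	3
V	GAC	2
V	TAC	5
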