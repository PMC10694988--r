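codon	anticodon	amino_acid	fraction_percent
TTT	GAA	F	2.353
TTC	GAA	F	2.353
TTA	TAA	L	1.176
TTG	CAA	L	1.176
TTG	TAA	L	1.176
TCT	GGA	S	2.353
TCC	GGA	S	2.353
TCA	TGA	S	1.176
TCG	CGA	S	1.176
TCG	TGA	S	1.176
TAT	GTA	Y	3.529
TAC	GTA	Y	3.529
TGT	GCA	C	1.176
TGC	GCA	C	1.176
TGG	CCA	W	1.176
CTT	GAG	L	1.176
CTC	GAG	L	1.176
CTA	TAG	L	1.176
CTG	CAG	L	4.706
CTG	TAG	L	1.176
CCT	GGG	P	1.176
CCC	GGG	P	1.176
CCA	TGG	P	1.176
CCG	CGG	P	1.176
CCG	TGG	P	1.176
CAT	GTG	H	1.176
CAC	GTG	H	1.176
CAA	TTG	Q	2.353
CAG	CTG	Q	2.353
CAG	TTG	Q	2.353
CGT	ACG	R	4.706
CGC	ACG	R	4.706
CGA	ACG	R	4.706
CGG	CCG	R	1.176
ATT	GAT	I	3.529
ATC	GAT	I	3.529
ATA	CAT	I	1.176
ATG	CAT	M	7.059
ACT	GGT	T	2.353
ACC	GGT	T	2.353
ACA	TGT	T	1.176
ACG	CGT	T	2.353
ACG	TGT	T	1.176
AAT	GTT	N	4.706
AAC	GTT	N	4.706
AAA	TTT	K	7.059
AAG	TTT	K	7.059
AGT	GCT	S	1.176
AGC	GCT	S	1.176
AGA	TCT	R	1.176
AGG	CCT	R	1.176
AGG	TCT	R	1.176
GTT	GAC	V	2.353
GTC	GAC	V	2.353
GTA	TAC	V	5.882
GTG	TAC	V	5.882
GCT	GGC	A	2.353
GCC	GGC	A	2.353
GCA	TGC	A	3.529
GCG	TGC	A	3.529
GAT	GTC	D	3.529
GAC	GTC	D	3.529
GAA	TTC	E	4.706
GAG	TTC	E	4.706
GGT	GCC	G	4.706
GGC	GCC	G	4.706
GGA	TCC	G	1.176
GGG	CCC	G	1.176
GGG	TCC	G	1.176
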