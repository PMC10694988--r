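pairing	s	description
WC	0	Watson-Crick
GU	0.41	anticodon G34 : codon U3
IC	0.28	anticodon I34 : codon C3
IA	0.9999	anticodon I34 : codon A3
UG	0.68	anticodon U34 : codon G3
LA	0.89	anticodon k2C34 : codon A3 (bacterial Ile AUA)
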