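name	site	cutOffset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
XbaI	TCTAGA	1
SalI	GTCGAC	1
PstI	CTGCAG	5
KpnI	GGTACC	5
SacI	GAGCTC	5
EcoRV	GATATC	3
SmaI	CCCGGG	3
DraI	TTTAAA	3
ScaI	AGTACT	3
SspI	AATATT	3
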