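name	site
AluI	AG'CT
BstUI	CG'CG
DdeI	C'TNAG
HaeIII	GG'CC
HhaI	GCG'C
HinfI	G'ANTC
MboI	'GATC
MspI	C'CGG
RsaI	GT'AC
TaqI	T'CGA
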