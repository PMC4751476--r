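aa	resid	ca	cb
A	ALA	52.5	19.1
R	ARG	56.0	30.9
N	ASN	53.1	38.9
D	ASP	54.2	41.1
C	CYS	58.2	28.0
Q	GLN	55.7	29.4
E	GLU	56.6	29.9
G	GLY	45.1	NA
H	HIS	55.0	29.0
I	ILE	61.1	38.8
L	LEU	55.1	42.4
K	LYS	56.2	33.1
M	MET	55.4	32.9
F	PHE	57.7	39.6
P	PRO	63.3	32.1
S	SER	58.3	63.8
T	THR	61.8	69.8
W	TRP	57.5	29.6
Y	TYR	57.9	38.8
V	VAL	62.2	32.9
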