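# General-purpose AAindex tables used by the consolidated-AAindex feature:
# Kyte-Doolittle hydropathy (KYTJ820101) and Hopp-Woods hydrophilicity
# (HOPT810101), as published. Values are z-scored over the 20 residues at load.
accession	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
KYTJ820101	1.8	-4.5	-3.5	-3.5	2.5	-3.5	-3.5	-0.4	-3.2	4.5	3.8	-3.9	1.9	2.8	-1.6	-0.8	-0.7	-0.9	-1.3	4.2
HOPT810101	-0.5	3.0	0.2	3.0	-1.0	0.2	3.0	0.0	-0.5	-1.8	-1.8	3.0	-1.3	-2.5	0.0	0.3	-0.4	-3.4	-2.3	-1.5
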