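# Synthetic stand-in values for four glycosylation-related AAindex accessions.
# The real AAindex database is not redistributable here; these values mimic the
# physical character of each index (sheet propensity, transfer energy, N-cap
# preference, loop information) but are NOT the published numbers. All
# downstream computation z-scores each row over the 20 residues, so a real
# AAindex table in the same format can be supplied instead via load_aaindex().
accession	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
KIMC930101	0.8	-0.6	-0.9	-1.1	1.2	-0.5	-0.8	-1.3	0.1	1.6	1.0	-0.7	0.9	1.4	-1.6	-0.3	0.4	1.1	1.3	1.8
LAWE840101	0.4	-1.4	-0.8	-1.0	1.1	-0.9	-1.0	0.0	-0.5	1.8	1.7	-1.5	1.2	1.9	-0.3	-0.5	-0.2	1.3	0.6	1.5
RICJ880102	-0.1	-0.3	1.6	1.5	0.3	-0.2	0.4	1.0	0.2	-0.8	-0.9	-0.4	-0.5	-0.6	0.8	1.4	0.9	-0.7	0.1	-1.0
ROBB760113	-0.9	-0.2	1.3	1.2	0.1	-0.1	-0.6	1.8	0.0	-1.4	-1.2	0.3	-0.8	-1.0	1.5	1.0	0.4	-0.5	0.2	-1.5
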