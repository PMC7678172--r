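symbol	accession	chrom	strand	cds_segments	cds_seq
SYNPLUS1	SYN_EX0001.1	1	+	1001-1006;1201-1203	atgaaataa
SYNMINUS1	SYN_EX0002.1	1	-	2001-2003;1901-1906	atgtgctaa
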