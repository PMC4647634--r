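chrom	length	strand	sequence
5	22	-	CAATTCCTTTGAGTTTCATTCT
5	17	+	GTGGCTGGATTGAATCC
8	22	+	ACAAGGAGGAAAAGATCTATCT
20	19	-	AGAGGTGAAATAGAATAAC
25	17	-	GTTTTCATGAGGCTGAT
28	19	-	CCTCTCAAGTCATTTCACA
45	23	-	CGGCACGAGCTGACGACAGCCAT
48	18	+	GAATCCGGGCCAGAAGCG
49	17	+	AGTCAGAATCCGGGCCA
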