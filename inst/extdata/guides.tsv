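name	spacer	pam
sgRNA1	GCTTAATTAAGGTAAACGTC	NGG
sgRNA2	CCAACCTGGCGGCTCGTTGG	NGG
EMX1	GAGTCCGAGCAGAAGAAGAA	NGG
VEGFA_site1	GGGTGGGGGGAGTTTGCTCC	NGG
Nanog_sg2	GATCTCTAGTGGGAAGTTTC	NGG
Nanog_sg3	GTCTGTAGAAAGAATGGAAG	NGG
CD2_1	ACATGGAAAGCTCATCTTAG	NGG
CD2_2	TACATGGAAAGCTCATCTTA	NGG
CD90_1	GCGGAAGACCCCAGTCCAGG	NGG
CD90_2	GTCCAGGTGGGAACTGGAGC	NGG
CD45_1	GTTTGTTCTTAGGGTAACAG	NGG
CD45_2	GAGTTTAAGCCACAAATACA	NGG
CD298_1	GACGGCAGTGAAGGGTGGGA	NGG
CD298_2	GAGTACTCCCCGTAACGAGG	NGG
safe_1	GTGCATTGTTGGTGGTTGTG	NGG
safe_2	GCTAAAGTATCAAAGGGAAT	NGG
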