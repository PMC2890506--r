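# Published genome-specific primer sets for the three homoeologous Wx and
# SSII genes of hexaploid wheat (forward row, then reverse row carrying the
# pair's annealing temperature, product size and chromosomal assignment).
name	sequence	tm_c	size_bp	genome
Wx-7A-F1	GTAAGCTTGCGCCACTGC
Wx-7A-R1a	GGATGCAGAATGCCACCTA	60	950	7A
Wx-7A-F2	CGCTCTGCATATCAATTTTGC
Wx-7A-R2a	ATATGCAAAGGAGGTGAGGAAC	60	1038	7A
Wx-7A-F3	CTGGTACGATCGACCGACAT
Wx-7A-R3	CGGCCCTTCACTCTTAGTTG	60	750	7A
Wx-4A-F1	AGCTAGCACCACTGTCTTCTGA
Wx-4A-R1	GGCCGTCCTATAGATGCCAC	60	854	4A
Wx-4A-F2	TCAACAACACCCAGCAGCTA
Wx-4A-R2	GGTTGGGGTCGATGACGTA	60	943	4A
Wx-4A-F3	CCACACACCCACACAAAGAT
Wx-4A-R3	TTTACACAAGGGATCGACGAG	60	731	4A
Wx-7D-F1	CCATGGCCGTAAGCTAGAC
Wx-7D-R1	CGCAAAATTGATATGCCTGTT	60	978	7D
Wx-7D-F2a	AACTACCAGTCCAATGGCATCTAC
Wx-7D-R2a	GCTCGGGAATTTCTCCTCAAT	60	938	7D
Wx-7D-F3	CCAGATCGTTCTCCTGGTACA
Wx-7D-R3a	CTCGCTCCCCTCGACA	60	861	7D
SSII-7A-F2	CCCAGAACAGAGTACCAGTGAAC
SSII-7A-R2	CGGATCTACAGGGCAGGTAA	60	953	7A
SSII-7A-F3	GCAGTCGGATTTCACAAATAAGG
SSII-7A-R3a	CCTGACGGTGTCGGAAGAT	60	883	7A
SSII-7A-F4a	AGCGAAAATGCAATCAAAGG
SSII-7A-R4a	TTTGGGTATGAGGGGGAAAT	60	1657	7A
SSII-7A-F5a	TGCACCATCGCTCGAAGT
SSII-7A-R5	CGTTGATGTGACACCATATCCT	60	983	7A
SSII-7B-F2	CTGTCAGCGACGTGGAACT
SSII-7B-R2	TGCATTGAAATGAAAGCTTGAC	60	947	7B
SSII-7B-F3a	GCAGTCGGATTTCACAAAGAAC
SSII-7B-R3	GGTCAGTAGGCCTTGGCTTG	60	973	7B
SSII-7B-F4a	CATTGACGCTCCTCTCTTCC
SSII-7B-R4a	TACTCCCACTATGGTTAGCCTTACA	60	1596	7B
SSII-7B-F5	ACAACTTCATGGGAACAAGGTT
SSII-7B-R5	CTCAGACCTGACGGAGATGG	60	949	7B
SSII-7D-F2a	GTCAGCGACGTGGAACAA
SSII-7D-R2a	CGCGAAACTAGCTCCCAATC	60	1053	7D
SSII-7D-F3	AGCCAGATTTCACAAAGAAGGA
SSII-7D-R3	AGTCAGTAGGCCTTGGCTTG	60	973	7D
SSII-7D-F4	CTCTCTTCCGACACCGTCA
SSII-7D-R4	GGAGAAGGAGAGGAGAAGTTGG	60	1654	7D
SSII-7D-F5	TGCGTCGCCTCATAGAGC
SSII-7D-R5	GCACAAGCAACTGACCTCAC	60	987	7D
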