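# Published classification of partial waxy wheat lines: presence (+) /
# absence (-) of the product of each diagnostic genome-specific primer set
# (Wx-7A-F1/R1a, Wx-4A-F2/R2, Wx-7D-F3/R3a) with the line's null-allele
# label and numeric type code.
genotype	accession	country	null_allele	type	wx7A	wx4A	wx7D
Chinese Spring	-	China	Wild type	1	+	+	+
Sturdy	CItr 13684	USA	null (Wx-A1b)	2	-	+	+
Fujimi Komugi	PI 360869	Japan	null (Wx-A1b)	2	-	+	+
Gabo	PI 155431	Australia	null (Wx-B1b)	3	+	-	+
Gamenya	PI 268329	Australia	null (Wx-B1b)	3	+	-	+
Santanta	CItr 14582	USA	null (Wx-B1b)	3	+	-	+
Bai Huo	PI 606717	China	null (Wx-D1b)	4	+	+	-
Kanto 107	PI 631445	Japan	null (Wx-A1b & B1b)	7	-	-	+
NSGC 8645	PI 612545	USA	Triple null alleles	8	-	-	-
NSGC 8646	PI 612546	USA	Triple null alleles	8	-	-	-
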