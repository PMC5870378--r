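genotype	tolerance	enzyme	unique_trf	total_trf
IR29	sensitive	DdeI	6	15
IR29	sensitive	HaeIII	3	9
IR29	sensitive	HhaI	5	15
FL478	moderate	DdeI	2	9
FL478	moderate	HaeIII	2	10
FL478	moderate	HhaI	1	12
IC27	moderate	DdeI	6	14
IC27	moderate	HaeIII	2	9
IC27	moderate	HhaI	2	12
IC31	moderate	DdeI	1	6
IC31	moderate	HaeIII	0	8
IC31	moderate	HhaI	3	12
IC32	moderate	DdeI	1	7
IC32	moderate	HaeIII	1	9
IC32	moderate	HhaI	1	12
IC37	high	DdeI	3	14
IC37	high	HaeIII	0	8
IC37	high	HhaI	1	11
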