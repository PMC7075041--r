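marker	chrom	repeat_start	repeat_end	structure	orientation	flank5	flank3	chrom_class
TH01	chr11	2171088	2171115	[AATG]n ATG [AATG]n	forward	CATACGCTTATCAAAGTATC	ATTGACTGTTTTTGCACTGT	autosomal
TPOX	chr2	1489653	1489684	[AATG]n	forward	CTGCTTGACTTTGGCGAATT	AACGTTAGATATTAAGGCTG	autosomal
vWA	chr12	5983977	5984044	[TAGA]n [CAGA]n TAGA	reverse	CACGGGATGACGAAAGAGTG	CAAGGACGACGCTGTATAAT	autosomal
D21S11	chr21	19181945	19182060	[TCTA]n [TCTG]n [TCTA]n ta [TCTA]n tca [TCTA]n tccata [TCTA]n TA [TCTA]n	forward	CTAGTAGGACATGACCGTGC	TCGGTGTAGTGGGTTAACAT	autosomal
D22S1045	chr22	37140287	37140337	[ATT]n ACT [ATT]n	forward	CCGGGGTATACCAGCTTTAC	ACCGGTGTATTTACCGTTCG	autosomal
D1S1656	chr1	230769616	230769683	CCTA [TCTA]n	reverse	GTCGTGTGGCTTTACTATGA	CAAGGGATTCGAAATCCGGA	autosomal
D12ATA63	chr12	93941632	93941678	[TTG]n [TTA]n	forward	CTGCGGGAGATCAGATTCGC	CACACTCGTCCGGGTCATCG	autosomal
DYS391	chrY	9767573	9767615	[TCTA]n	forward	CGTACCTGCGAGGAGCTTGG	TCATTGGGGGATATGGGCCA	Y
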