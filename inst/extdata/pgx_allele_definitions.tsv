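# IWPC-relevant defining variants (GRCh37 coordinates, dbSNP/PharmVar)
# VKORC1 allele "A" is the -1639G>A promoter allele (rs9923231; plus-strand C>T)
gene	allele	genome_build	chromosome	position	ref_allele	alt_allele	rsid
CYP2C9	*2	GRCh37	10	96702047	C	T	rs1799853
CYP2C9	*3	GRCh37	10	96741053	A	C	rs1057910
VKORC1	A	GRCh37	16	31107689	C	T	rs9923231
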