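# SYNTHETIC placeholder weight table for the 11-SNP LDL-c-raising panel.
# Effect alleles follow published GLGC orientations (the LDL-c-raising allele
# is counted, except APOE rs7412 which is carried on its epsilon2-defining T
# allele with a negative beta so that E2/E2 genotypes score below zero).
# Betas are approximations in mmol/L per effect-allele copy; replace with the
# exact GLGC coefficients for production use. ref_freq is an approximate
# European effect-allele frequency used as the simulator default.
rsid	gene	effect_allele	other_allele	beta	ref_freq
rs2479409	PCSK9	G	A	0.052	0.35
rs629301	CELSR2-SORT1	T	G	0.150	0.78
rs1367117	APOB	A	G	0.100	0.33
rs4299376	ABCG8	G	T	0.071	0.31
rs1564348	SLC22A1	C	T	0.014	0.17
rs1800562	HFE	G	A	0.057	0.93
rs3757354	MYLIP	C	T	0.037	0.77
rs8017377	NYNRIN	A	G	0.029	0.45
rs6511720	LDLR	G	T	0.180	0.89
rs429358	APOE	C	T	0.240	0.15
rs7412	APOE	T	C	-0.450	0.06
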