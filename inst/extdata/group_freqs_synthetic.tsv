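# SYNTHETIC group-specific effect-allele frequencies used as simulator
# defaults. EUR values match the ref_freq column of the weight table; the
# mutation-negative (fh_mneg) column enriches the panel SNPs that associate
# with FH (and depletes the protective APOE epsilon2 allele) so that the
# simulated 8-SNP score separates cases from controls with a mean gap of
# about 0.10 on a within-group SD of about 0.2; the mutation-positive
# (fh_mpos) column applies roughly 40% of that shift.
rsid	eur	fh_mneg	fh_mpos
rs2479409	0.35	0.410	0.374
rs629301	0.78	0.835	0.802
rs1367117	0.33	0.380	0.350
rs4299376	0.31	0.400	0.346
rs1564348	0.17	0.170	0.170
rs1800562	0.93	0.930	0.930
rs3757354	0.77	0.810	0.786
rs8017377	0.45	0.450	0.450
rs6511720	0.89	0.925	0.904
rs429358	0.15	0.180	0.162
rs7412	0.06	0.025	0.046
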