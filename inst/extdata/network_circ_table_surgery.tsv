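circRNA	log2_fold_change	p_value	regulation	circRNA_miRNA
mm9_circ_006949	1.08	0.0449	Up	mmu-miR-615-3p
mm9_circ_007155	1.24	0.0497	Up	mmu-miR-296-5p
mm9_circ_010522	1.30	0.0466	Up	mmu-miR-298-5p
mm9_circ_013251	1.28	0.0489	Up	mmu-miR-1966-3p
mm9_circ_014796	1.19	0.0350	Up	mmu-miR-298-5p
mm9_circ_016411	1.21	0.0216	Up	mmu-miR-615-3p
mm9_circ_018802	1.24	0.0459	Up	mmu-miR-1264-5p
mm9_circ_009789	1.98	0.0003	Up	mmu-miR-298-5p
mm9_circ_008009	1.48	0.0316	Up	mmu-miR-298-5p
mm9_circ_004229	1.52	0.0109	Up	mmu-miR-298-3p, mmu-miR-298-5p
mm9_circ_007503	1.31	0.0042	Up	mmu-miR-298-5p, mmu-miR-615-3p
mm9_circ_011555	1.50	0.0149	Up	mmu-miR-122-5p, mmu-miR-615-3p
mm9_circ_003736	-2.46	2.93E-18	Down	mmu-miR-18a-3p, mmu-miR-298-5p mmu-miR-615-3p
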