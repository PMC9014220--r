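circRNA	log2_fold_change	p_value	regulation	circRNA_miRNA
mm9_circ_001571	1.55	0.0197	Up	mmu-miR-296-5p
mm9_circ_002005	1.27	0.0010	Up	mmu-miR-298-5p
mm9_circ_002179	1.25	0.0024	Up	mmu-miR-7056-5p
mm9_circ_002489	-1.11	0.0196	Down	mmu-miR-296-3p
mm9_circ_000550	-1.66	0.0025	Down	mmu-miR-6938-3p
mm9_circ_003736	-2.71	6.88E-27	Down	mmu-miR-298-5p, mmu-miR-615-3p, mmu-miR-6938-3p, mmu-miR-7056-5p
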