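mirna_id	gene_id	r	padj
miR-31-5p	SYDE2	-0.91	4.00e-04
miR-26a-5p	RGS4	-0.88	8.00e-04
miR-224-5p	FBXL3	-0.82	2.80e-03
miR-26a-5p	CA2	-0.78	6.20e-03
miR-142-3p	CCNT2	-0.77	6.60e-03
miR-142-3p	ADAM22	-0.76	7.90e-03
miR-142-3p	CYP1A1	-0.73	1.20e-02
miR-142-3p	PPM1K	-0.71	1.50e-02
miR-212-3p	FAM76B	-0.71	1.60e-02
miR-224-5p	SLC25A36	-0.71	1.60e-02
miR-142-3p	VPS13A	-0.70	1.90e-02
miR-142-5p	VPS13A	-0.68	2.30e-02
miR-142-3p	SIAH1	-0.65	3.30e-02
miR-142-5p	CCNT2	-0.63	4.10e-02
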