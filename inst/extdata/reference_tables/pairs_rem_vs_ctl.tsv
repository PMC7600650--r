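mirna_id	gene_id	r	padj
eca-miR-142-3p	ADAM22	-0.92	1.00e-03
eca-miR-142-3p	GORAB	-0.78	1.70e-02
eca-miR-142-5p	ARID1B	-0.71	3.30e-02
eca-miR-142-3p	NR3C2	-0.69	3.70e-02
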