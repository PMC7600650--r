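mirna_id	gene_id	r	padj
eca-miR-146b-5p	OSGIN2	-0.82	4.7e-02
eca-miR-146b-5p	UBTD2	-0.82	4.7e-02
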