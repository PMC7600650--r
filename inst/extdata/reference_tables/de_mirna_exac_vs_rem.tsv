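mirna_id	base_mean	log2fc	padj
eca-miR-NW_019643269.1_38788	3512	-2.6	6.00e-03
eca-miR-146b-5p	7515	2.3	9.00e-03
eca-miR-135b	14	4.08	4.60e-02
eca-miR-31	560	2.17	4.60e-02
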