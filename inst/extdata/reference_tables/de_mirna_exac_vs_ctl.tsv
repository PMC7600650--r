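mirna_id	base_mean	log2fc	padj
eca-miR-142-3p	7016	0.69	6.30e-05
eca-miR-26a	576062	-0.38	8.70e-03
eca-miR-142-5p	107984	0.51	1.00e-02
eca-miR-31	561	2.11	1.20e-02
eca-miR-212	17	2	1.50e-02
eca-miR-223	5088	1.16	1.50e-02
eca-miR-224	10	2.28	1.50e-02
eca-miR-chrX_37753	37418	0.40	1.50e-02
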