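mirna_id	base_mean	log2fc	padj
eca-miR-NW_019643269.1_38788	3512	3.36	2.52e-07
eca-miR-142-3p	7016	0.63	1.00e-03
eca-miR-142-5p	107984	0.59	2.00e-03
eca-miR-chr15_8716	20	-2.57	2.00e-03
eca-miR-chr7_32350	2186	-2.01	7.00e-03
eca-miR-chrX_37117	790	-1.76	7.00e-03
eca-miR-363	453	-0.61	2.70e-02
eca-miR-379	16	-1.97	2.70e-02
eca-miR-193a-3p	430	1.02	3.00e-02
eca-miR-chr6_31338	323	-1.53	3.00e-02
eca-miR-223	5093	1.04	4.60e-02
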