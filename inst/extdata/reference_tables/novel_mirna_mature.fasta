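>eca-miR-NW_019643269.1_38788
gccgaucgaaagggagucgg
>eca-miR-chr15_8716
accuggggaucugaggagg
>eca-miR-chr7_32350
aucccaccacugccacca
>eca-miR-chrX_37117
uuccccggcaucuccucca
>eca-miR-chr6_31338
uccccggcuccuccacca
>eca-miR-chrX_37753
agagguaaaaaauugauuugacu
>eca-miR-chr6_31290
ugagguaguaguuugugcuguu
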