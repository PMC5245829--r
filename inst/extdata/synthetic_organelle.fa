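>synthetic_organelle_1
AGGGTACCACGTAACTGACGGACCAACTGTCTAAGTTTCAGGCGATCGAGTCTCCGTGACCTAAGTACTAAGGAAGAGGCCGACTAGACTTACTCACCGCGGTTAGAAAGCCAGACCAGTTGTTATGGGGCATGCAGACACCCCAGGCTACTTCGACCCTAGAGAGAACCGTTCGAATCGCCCATGCCATAAGAGATCAA
>synthetic_organelle_2
CTCTGCACTGACCATCTCGCCGGACCACCGCACTATGCGAAGATACCTAGACTGTGAGAATGGTGGGCCTCCTAGCCGTCAGAACGCCAACAGTCTTGATACTCGGCTATACTATGGTGATTCTAATAGGTCCTCGCGTTAAGCTCAGTTGAGGAACGACACCCGTATACAGGCATCGGG
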