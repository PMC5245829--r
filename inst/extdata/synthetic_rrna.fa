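>synthetic_rrna_1
AAAACGAAACGCATTAATTTAGGAGTGCTGATTATAGCGAGGCTGGAAGGGGGCGATGCTCTAAAAACACGGATAGACCCGGTCTAGCCGTGGTGAAACAAGATTACATCTTTAAAACCTAAACTTGACCCTTTCTACCGGGGGGTGGGCCCTTCCTAAC
>synthetic_rrna_2
CCGCGAGTCGTGGTTACATCCGAGCTGGGACACTCATGGCTCAGGTTCACGACGCAGCCCGCCTCCATATCGCGATGTCCCGCAGGTCCCTGCCATCACGTAATCTTGGCTATCCCATGGCTGTTACTTTTCCTTTGCTA
>synthetic_rrna_3
GTAACATGAATCCGGAGCTAGCATCGTCCTCACTGACCAGCCTGAGAACACGGAAACTGACAGAGAGTTAGTCTTTACGGGCGCATGAACCTTCACCAGAACCGAGCTGGTTCAGAAGTA
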