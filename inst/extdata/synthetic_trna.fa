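>synthetic_trna_1
CATGAGGGACAACTATGCGCCGCAAGCTTCTTTGGAGGGCGCAACAAGCGTTCAGGGCGCCATAACCGCTTTAGA
>synthetic_trna_2
GCTCCATAGGCACCGCCGCCCCAGCTTACCGTGCGTTATTGTCTAGCTCTATCTCACTCCAGTGCTGCTCCTTAGGCGTT
>synthetic_trna_3
CTATGCTTCACCATTAGCATTGATTTGCTCCTCCTTAACTTGTGATCGTCCACAACTTCTCATGGAACACTT
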