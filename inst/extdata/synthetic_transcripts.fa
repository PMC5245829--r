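>synthetic_lbp_like
TCCTGAACGCACTCACCCAGACGGTCAGGTAAGATAGCTCATGACGCATCTAGTTAGAGTTTCAGACGAAGACCCCCAGTATCTTCTGCCTAACGACGTAGTAACCTCTCGTTTATGCAGGGTTTACCGCAAATATCCTATAAAGGGTACACTAGCCGCGTGTGCCTCAAAATCCGATAAAGCGACGCCTTACGTCCAGCCTTAGTGAGCTCATGACCTGTGCCCGATCAGGTTTCTTCTAACACGGAGCACTGCGATTATATTCATCAGTCGAAATGTCGCATCTTACTTCACTGGCCA
>synthetic_tx_2
GATGATACTACGCGATAATGAACCGATCGGGGAAGCTGTAGCTAGTTTCTATCATGCCAACGTCCCCTTAGACATGAGGCCCCAAGCACACAAATAAATGAGCGGTTCGCCGTCTCGGCCGCACTCGAACTCCGTCCCTAGCGGTTCTTTTTGGATCCGGGAGTGTGACGACTGCACGATATTGAAGTTGCACAAACTCACAAGGCCGGGGGTCTAGCGATTCAGCGTTAAGCATCCATGACTCCGCGGCCATCCGTAAGTGTACTCTTATTGTCAGATCTAGCATATACGTGACATCTTATGCGCACTTGGACCAAGAT
>synthetic_tx_3
CTAAGATCCAAAGGCGTAGGTTTTCGTCAGGACAATATACACCCAGGGCTTCAACTCTGCATTTCACTAGCAGCATCGGCGATGTTTCATGTTTATCGCCGGTCGGGGCCCGCACTTAGGATTCAGCACAGTAACCGTAGGCTAAGTTAACCTGTCGCCCGCTAAGTGGCGCTGTTCGAATTCAGGATCGTAGCTGTTGTGTCAAAAGGCAGCTGCTCTTCTTTCCACCTTGTGGATTAAAATCTAAGCTCCCGTATAGCTTCCTCCCCCTGGGTCACCA
>synthetic_tx_4
AAGCCTATTTTTTTGATCTGCCTCACTGCTGAGGTAGACCACCGCGCCATTTCAATTGTTTACACTTCGGCGTCCGAGGAGCACTCCCGTAGAAGGGTACGCACCAGCAGTATTCTAATGCTCAGTTAGTTGGTGACCCGACAAACTCGCTAGTGAGTGTTTAACGGATAGTACTGCCACTGTCGACTGACTTGTCGCCTCGGCACAGCTCGTCATCGTGGAGGATCGACCCATTCGGTTGCCTCGAGTCTTAGCGGTAGATGGGATATAACAGGGAGGACGTTGGTGATCGAGCACACG
>synthetic_tx_5
GGTACTCGGCGTTTATCCGATTTAAAATTCTTAGCAAGTTGGTGATAATCAGCCAGAGGCATGCGGACTCCCGGGAGAGACGTGACGTATTGTTCCGCTGGATCCGTTGTGTGTTCCCCGGTACTCGCCCGCAACCCCGTTAATGTGCTATGGCTAGAACAGCGGCAAGAAAGCGAAACGTAAGTGTCGCAGCCATACGACGGAGGGAACGCTAAAGCACTGTTGGCTGCAAGGTAAGACTTACGACGCCATTTACACCG
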