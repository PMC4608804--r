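>EGFR:60-260
TGGCTGTTAGTACTTTCACAAACATACCATAGGGAGTGCAGCCCTTGTGACGCCTCCAGCTAGCGGCGGTCCACCGTGTG
GTACCTTCCCATTTGTACCGACCGCGGCATGACTAAATCGATGGACCGGCCAGGCTTCATGAGTCAATTCCCATCCCGCT
CTGATCCCGCGGATACCAATAATTAGCCTGGTGCTAATGT
>ERBB2:60-260
ATGCCGATGCCTCTGCGGTCGCCGGTAGGTCCGCAGCCTGCCGGGTTGTGAGAGACGCCCCTCGGCAGCTCGTTTAGATC
TGTCCGTGCGTATCATGGGGAATGGTGGGTCGAACAGTTCGCGTAGCGGGACGTCGGATTCTGCGGCCGCACTGCCTTGA
GCTCTCACTCCGCACGTTAGCGGGTCGTCCCCAGGGATCC
>MET:60-260
CTCGGTGCCACGCTAGCGCACCAGACCCGTTCTTTCGCGGCAAAGCTGCGGCTCGCGACCTACCCATCGCCTGTCAACCA
GCGGCCTCGTAGCGAGTTCAGACACAATATGCCGTCCGTATCGCGGAGAATTGGAAGAAGCGGCACCGCTTGCGCGTGAG
GCATCAGCCGCGACTTTCCGCCTCCCACGTGGCGTGACGC
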