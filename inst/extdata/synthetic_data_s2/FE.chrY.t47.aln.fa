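>FE.chrY.t47_chrX
GGCGACGGTACGCCAGCGCTTACAAAAATTCACACCGTTCATCACATCCCTTGACTATAACTTGACCATCAGTGCGCGTT
GTCGCCCTGAGCGGCCAGACTGCCTTCGTCATAGTATTGAAATTCATATCAAATACGAAAGTATGACGGGCGAGGGTGCA
CGGAGACTTTGAGTCAGATGGCCCCAGATCATCATCTTAGTGAGACCAGTAGGGCTGAGTATATATCCCGGTGAAGACGA
TTCCCCCGCACACCTTATGTATCGACTGTTTCTCGATTTAGCCCCAGAGCATTTACTGTATGGGTTCGAAGTAGCGTGCC
TATTAATCCTCCATGTTGTCTAGTACATCCATAACGGCCAGGATGGTATCTCGTACGATAGAGAGCGATTTTTAGCCGGT
CGGATAATATGCCGTCCGACACGTTCCAAGCGACCAGACGATAGACAGTTTACTAACCTTCATGCACGCTACGTTTAATG
TTTAGGGCACTTTGGCCACCTCTCAAGGTGACGCCCTTTACACTAGCATTTTGATCATTATTCCTGTCTATTCCAGAAGA
CAAGGGACATGCGTTTACTCCTTATGGAATCACAGGACGATCAGATCGTTGTGAACGAATGCTAGCGTAATGTCGGAGTT
CCTAGCGGGGGTTAACGTCTTGGACCACGTAAGTTCCATTATGTATGTGAAGACGCCGGGCCTTTAAGGTCTATAGATGT
CTACGTGTACGGTGCTTGCGCAGAGGCCAGAAAGCAGTAAAAAGTGCAGCGCACACCTCCGTGAACAACTCTCCGTTGTG
>FE.chrY.t47_chrY
GGCGCCGGAACGCCAGCGCTTGCAAAAATTCACACCGTTCATCTCATCCCTTGAATATAACTTGACCATCAGTGCACGTT
GTTGCCCTGAGCGGTCGGCCCGCCTTCGGCATAACTTTGAAATTCATATCAAATATGAAAGTATGACGGGCGAGGGTACA
CGGCGACTTTGAGTCAGATGGCCCCAGATCAGCATCTGAGTAAGACCAGTAGGGCTGAGTATAAAACCCGGTGCAGACGA
TTCCCCAGCACACCTTATGTATCGACTGTTTCTCGATTTAGCCCCGGAGCATTTACTGTACGGGTGCGAAGTAGCGTGCC
TGTTAATCCTACATGTTGTCTAGTACATCACTAACGGCCAGGATGGTAACTCGTATGATAGAGATCGATTTTTAGCCGGG
AATTCTATTTGCCGTCCGAAACGTTCCAAGCTACCAGACGATAGACAGTTTACTAACCTCCATGCACGCTACGTTTACTG
CTTAGGGCATTTTGGCCTCCTCTCATGGTGACGCCCTTTACACTAGCATTTTGATCATTATTCCTGTCTATTCCAGAAGA
CAAGGGACATGCGTTTACTCCTTATTGAATCTCAGGACTATCACATTGTTGGGAACGAATGCTAGAGTAGTGTCGGAGTT
CCTAGCGGCGGTTAACGACTTGGACCACGTAAGGTCCATCATGTATGTGAAGACGCCGGGCCTTTAAGGTCTATAGATGT
CTCCGTGTACGGTGCTTGCGCAGAGCCCAGAAAGCAATAAAAAGTGCAGCGCACACCTCCATGAACAACTCTCCATTGTG
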