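>FE.chrY.t42_chrX
CCCATTCTTATGAACTCCGGTTCTTCTGAGTAAATGACACACCCTACACGTCTTCGTTTCATCAGCCACGTATTTGTCAA
CATAGTGGGGATTTTAACTGACTTGTGTACCCATCCTACGCGTTCAAAGGAGCCGGCGATCACTGCTCTGTCCGTAGATG
AAGACGATCACGCTAGAGAGTCGGTCCTAAAAGCCGGCCCTCAGGTTGTAATTAGAGCTTCCGCATCCCTGACGCGGTCG
TGAAGTAGCCTTTACATGCATTTTTGATGATAGTTCCTTCACCACGCACGTTGGTACCGCTGTTCAAAAATCGGCGGAGA
CACGTGCAAACGCACTTCCGATGGAAAACTGAACAAACGTAACGATCATGGTGCATGTCTTCGTCGAATAGTCCCCCTCT
GGGGTCGAATTGCAGACCAACCACTCACGATTCTGGAGGCTCCCACCGCTCGATACACCTAGGACTCTGTATGTCGCCAG
GCTTCTGTACTTTGGAGCACAATTGCGACATTGGCACGGAATGCCGGAGAACTCGGAATGCCACTGCAACTGCCGCCATA
TGAGAAGGTTAAAACTTCGCTCTAGTCTACCCGCCAGAGCCAATGGGCTGAAAATCAAAGCGATGTTGAAAGGTCAGTGG
TTTCCTCGATGACTACGATTTGGTTACTTCAAGGAGGTTCATGCCATTGCACGAAGAAACTCCTGACCGGCAACGAGATA
ATGCAGAAGAGCGCACGAAGTAGTTTCCCCGGAACTAGTGTGAGTGTGCCTAGTGCGTTCGATGAGTATCTCGACCCCAG
>FE.chrY.t42_chrY
CCCATTCTTATGAAGTCCGGTTCTTCTGAGAAAATGACACACCCTACACGTCGTCGTTTCATTAGCCACGTATTTGTCAA
CATATTGGGGATTTTAACTAACTTGTGTACCCATCCTACGCGTTCAAAGGAGCCGGCGGTCACTGCTCTGTCCGTAGATG
ATGACGATCACGCTAGAGAGTCGGTCCTAAAAGCCGGCCCTCAGGTTGTAATTAGAGCTTCCGCATCCATGACGCGGTCG
TGAAGTAGCCTTAACATGCATTTTTGATGATAGTTCCTTCACCACGCACGTTGGTACCGCTGTTCAAAAATCGGCGGAGA
CACGTGCAAACGCACTTCCGATGGTAAACTGAACAAACGTAACGATCATGTTGCATGTCTCCGTCGAATAGTCCCCCTCG
AATTCAGAACTGCAGACCAACCACTCACGATGCTGGACGCCCCCACCGCTCGATACACATAGGACTCTGTATGTCGCCAG
GCTTCTGTACTTTGCAGCACAATTGCGACATTGGCACGGACTGCCGGAGAACTCGGAATGCCACTGCAACTGCCGCCATA
TGCGAATGTTAAAACTCCGCTCTATTCTACCCACCAGAGCAATTGGGCTGAAAATCAAAGCGATGTTGAAAGGTCAGTGG
TTGCATCGATGACTACGATTTGGTTACATCAAGGAGGTTCATGCCATTGCACGAAGAAACTCCTGACCGACAAAGAGATT
ATGCAGAAGAGCGCACGAAGTAGTTTCCCCGGAACTAGTGTGAGTGTGCCCAGTGCGATCGATGAGTATCTCGACGCCAG
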