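>FE.chrY.t25_chrX
ACCTAATGACCACCGCGAATGTGTCTTGCAGTGCAAGTAAACGGGAACGCCTGAATTATGCCACCAGGGCGGCAAGCGAC
CTAGGATTGTTATCGTACGCACCCAGAGCAACGTCTCAGCGGACCACAGGGGAAATATCATCTTACAAAAGGCGCGGGAC
TCATTAGTGGACCGGCGTCACGAATGGCGCACCTAGCCGTATTAACACTGAGTGCGAGAATGATATATCACTACACCCAT
ACTTCGGACCGAGATTAGTTTACTGAATCACTCCTTGATAGTGGCATTTCTCTGGGGGACGACCAGTTCTGAGGGTCGCG
CTAGTATCAATTGTGTAAATACCCGCACTCAGGATCAATCTGTCCCCTACGAGTGATAGGCCCGCGTCGAATACTAGTGT
TGCCACTCGTCATTTCATGGGGGACGCAATACGTCGCGTGGTCAAGTACTAGACAGAATGGGCGAAAGCTTAACTTGCTA
CGCCCGCGAGGTCCGCCTGTGCTGGCTTGCATGCATTAGCCCCACCCGGCTGTACCGCTCACGGAAGATAGAAAATGTTC
GGGGAGTTCTATCATTAACCCAGAGAGCATGGATAGTATGACTCCCCCCGGCTGGCGAAGGCGACGAACTTTTAAAGAAC
TAGTCTAAGTATTATCTGGACAACATTTGCGTCACACGGCGTCGGAACTTCGCCAGGGGTGACAGGAAGATTTGGTCGCG
GGTGATTGAATAGGCTAGATAATATTGGACCTGAAGTATATACGATTGACTTGCGTAAACCAAGGAGGAACCACATGTGT
>FE.chrY.t25_chrY
ACCTAATGTGCCCCGCGAATGTGTCTTGCAGTCCAAGTAAACGGGAACGCCTGAATTATGCCACCAGGGCGGCAAGCGAC
CTAGGATTGTTATCGTACGGTTCCAGAGCAACCTCTCAGCGGACCACAAGGGAAATATAATCTTACAAAAGGCACGGGAC
TCATTAGTGGACCGGCGTCACGTATGGCGCACCTAGCCGTATTAACAGTGAGTGCGAGAATGAGATATCACTACACGCAT
ACTTCGGACCGAGATTAGTTTACTGAATCACTCCTTGATAGTGGCATTTCTCTGGGGGACGACCAGTTCTGAGGGTCGCG
CTAGTATCAATTGTGTAAATACCCGCACTCAGCATCAATCTGTCCCCTACGAGTGATAGGCCCGCGTCCAATACTAGTGG
AATTCCTCGTCATTACATGGGGGACGCAATACGTCGCGTGGTCAAGTACTAGACGGAATGAGCGAAAGCTTAACTTGCTG
CGCCCGCGAGGTCCGCCTGTGCTGGCTTGCATGCATTAGCCCCACCCGGCTGTACCGCTCACGGAAGATAGAAAATGTTC
GGGGAGTTCTATCTTTAACCCAGAGAGCATGGATAGGATGACTCCCCCCGGCTGGCTAAGGCGACGGACTTTTAAAGAAC
TAGTCTAAGTATTATCTGGACAACATTTGCGTCACACGGCGTCGGAACTTCGGCAGGGGTGACAGGAAGATTTGGTCGCG
GGTGATTGAATAGGCTAGATAACATTGGACCTGAAGTATATACGATTGACTTGCGTAAACCAAGGAGGAACCACATGTGT
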