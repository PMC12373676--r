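>FE.chrY.t122_chrX
TTGCTTTGTAGGGCTATCGGCCAACACGTTAGAATGTAATCTACACGATGTACCGGCTTCGGAAGCTAGTCTGCGGATTG
GGCTCCTAACCACAGTAACTTCTGTGGTATTGGCTAACCACCATTTCCTGCCCAGTTTTCTCTCTGGAACCGTTTTCCAA
AGCATCACTTCTGCAGCGACGATGATCCTGGTGGATCGCGGGCTAGCATGAGTTGATTCCGAATGTTCAACCATTCCTTA
TGCACGTGGCCGGCGTTGTTCCGCCGCATCTCAGGTTCCTGACGACATTCGTCATGGCTGAACAGGGAACGCATATGAGA
TAAAAGGGTAGATTGAAAAAGACGCACGGTGTCAAGGGTCGACGAGCATGACAGATTCCCGATTCAGTTTAAAGATATTT
TCGCTCTCTCCGGCCCCCTGGTGACGATATCTGGTATAAATCAAATTGCCTGCGGTGACACTCACACGCCTCAATACCTA
CTTGAAATCTTTTAAACAGAGAGTCGCTATACTGAGGATCATGCGTCGTCGACACTGTGCCAGTAAGGCATCGCGATACC
CCCGAGGACCGGATCGTTAAGGCACGACCAGCAGGCATTTTCTGATGATGACAAGCCGGCCATTTCGAATTTGTGAAAAT
CCATATCCGCAAGTAGTGTGATGGTTTCTCCCAACTAACAAAAGTTACGTAGGAAATCAGCCGATGGCCGGTAGCCAGAG
TGTGCCGAAACTCGTATGAAAGGAACCACAACGGTCGAGCATAGCTTATACTAAAATCCACTAACTAGTTCAAGAGAAAT
>FE.chrY.t122_chrY
TTGCTTAGTAGGGCTATCGGCAAACACGTTAGAATGTAATCTACACGATTTACCTGCTTCGGGAGTTAGGCTGCGGATTG
GGCTCCTAACCACAGTAACTTCTGTGGTATTCGCTAACCACCATTTCCGGCCCAGTTTTCTCTCTGGAACCGTTTTCCAA
AGCATCACTTCTGCAGCGAAGATGATCGTGGTGGATCGCGGGCTAGCATGACTTTATTCTGAATGTTCAACCATTCCTTA
TGCACGTGGCCGGCGTTGTTCCGCCGCATCTCAGGTTCCTGACGACATTCGTCATGGCTGAACAGGGAACGCATATGAGA
TAAAAGCGTAGATTGAAAAAGACGCACGGTGTCAAGGGTCGACGAGCATGACAGATTCCCGTTTCAGTTTAAAGATATTG
AATTCCTCTCCTGCCCCGTGGTGACGATATCTGGTATAAATCAAATTGCCTGCGGTGACACTCACACGCCTCAATACCTA
CTTGAAATCTTTTAAACAGATAGTCGCTATACTGAGGATCATGCGTCGTCGACACTGTGCCAGTAAGGCATCGCGATACC
CCCGAGGAACGGATCGTTAAGGCACGACCAGCAGGCATATTCTGATGATGACAAGCCGGCCATTTCGAATTGGTGAAAAT
CCATATCCGCAAGTAGTGTGATGGTTTCTCCCAACTAACAAAAGTTACGTAGGAAATCAGCCGATGGCCGGTAGCCAGAG
TGAGCCGAAACTCGTATGAAAGGAACCACAACGGTCGAGCATAGCTTATACTAAAATCCACTAACTAGTTCAAGAGAAAT
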