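>CsPDS5like_chrX
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGCAGTACTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>CsPDS5like_chrY
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGAATTCCTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
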