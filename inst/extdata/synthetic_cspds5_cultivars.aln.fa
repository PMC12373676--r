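>REF_chrX
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGCAGTACTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>REF_chrY
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGAATTCCTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>GRM_chrX
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGACTATCATCCAGAGACTGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGCAGTACTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCCTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>BCM_chrX
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGACTGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGCAGTACTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCCTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>AH3M_chrY
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGACTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGAATTCCTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
>KOMP_chrY
CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAGAGCTCCACCGCCTGAAACT
GTATGCTGGCCCCTCCTCCCGGATTATCATCCAGAGAATGTGATAGCGGATGATTCGAGATATTTCATTGGAGCTTCTCA
CCAGTTCGGTACTCAAGATATCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGG
CCTGAGTTACAGTTTGGAATTCCTTTGACGCTTACTGCGCCGATCCGCCTTACTTCACCATGCCTCTATCGAGCCTATCG
AAATCTGTGCTCCTAAGGTTGGCAAAAGCCTAGGATATGTAATACGTAGCCCGGGCCAACCGAAGTTAAGTCTCAGACCC
ACGATACCTTGGGGATTGTATTATCAAATCCAATTCTCGTACAACTCTTTGCCTTCTCGGTCCTGAAATACAGTTCTGTA
CTTCATGTACCGTAGAGTGCTTCTGATGAGAATATGGTACGTGGTCACAACCTAGAGGGGCGTAGGAATTTCAACGTGAA
GCAATTGGACCCATGAAGGTACGGAAGGGACGCTGTGTC
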