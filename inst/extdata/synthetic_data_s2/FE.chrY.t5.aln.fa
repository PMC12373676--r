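>FE.chrY.t5_chrX
CAGCCTATAACTCACTCAGTAGCCGTTGTAAATGGCAGCTTGCGCTGGTCCTTGTCTTCTAGATAGCTATAGGGACCAAA
GTAATGGACAACAACAACACCCAACCGTTGCATCTACGTATCATGTACGACTTCCCTCGCAGGGGAACCGGACACCCATC
CGCAATGCTGGGTCTGTTCGTAAGCCGCAGACGCAAAAATAAGCGAGTACGAGCTGAGGGGAGAGTTATGCTCCCACCCC
CAGTTGTGGAGTGGAGACCTCACTGTTTACGACTCGTCGGTTTAAATATCGGTCAATTGTGACAACCAGATCGTGAAACA
GAGCTTTTGGCTAGCGTAGTGGGGAATGTAATCCATTGAGGCCGTTGTTCCGCTTCACGTCTAATACCGTGGGATTCCAA
CGAATCACCATCTGCTGCGCAGCTTAAGTTACGAGGAAATCCTCCAAATAGTTCTTCACGTACTGGCATGGGGGCATAGT
CACCTTGAGCTGCCTGGATCATGTCGTCGTTACCCATACGTGCAGAGCTCTATCTCGTGGCTTGGCGCGGATCTCGAGGG
GGAACCGTCGCTCACTCGTGTTACTCAGTTTACTGGCGTGCCCACGTTCCATCAAGTGGCGGTATATCTAGATTCGGTAG
AACACAACCCCATAAGACAACTGAGGTACCTAGGAGATAGCGCAGATCAACAAATCATAAAGCTAAGTTGATGAAAGACG
GAGGGTTCAGGTCGCAGTCGTGGTACCTAAGGGCCATCTAAGGTAGGCCGTCCGCGAGATCCGACCTGTAATGAGGATAC
>FE.chrY.t5_chrY
CAGCCTATAACTCACTCAGTAGCCGTTGTAAATGGCAGCTTGCGCTGGTCCTTGTCTTCTAGATAGCTATAGGGACCAAA
GTAATGGACAACAACAACACCCAACCGTTGCATCTACGTATCATGTACGACTTCCCTCGCAGGGGAACCGGACACCCATC
CGCAATGCTGGGTCTGTTCGTAAGCCGCAGACGCAAAAATAAGCGACTACGAGCTGAGGGGAGAGTTATGCTCCCACCCC
CAGTTGTGGAGTGGAGACCTCACTGTTTACGACTCGTCGGTTTAAATATCGGTCAATTGTGAGAACCAGATCGTGAAACA
GGGCTTTTGGCTAGCGTAGTGGGGAATGTAATTCATTGAGGCCGTTGTTCCGCTTCACGTCTAATACCGTGGGATTCCAG
AATTCCCCCATCTGCTGCGCAGCTTAAGTTACGAGGAAGTCCTCCAAATAGTTCTTCACGTACTGGCATGGGGGCATAGT
CACCTTGAGCTGCCTGGATCATGTCGTCGTTACCCATACGTGCAGAGCTCTATCTCGTGGCTTGGCGCGGATCTCGAGGG
GGAACCGTCGCTCACTCGTGTTACTCAGTTTACTGGCTTGCCCACATTCCATCAAGTGGCGGTATATCTAGATTCGGTAG
AACACAACCCCATAAGACAACTGAGGTACCTAGGAGATAGCGCAGATCAACAAATCATAAAGCTAAGTTGATGAAAGACG
GAGGGTTCAGGTCGCAGTCGTGGTACCTAAGGGCCATCTCAGGTAGGCCGTCCGCGAGATCCGACCTGTAATGATGATAC
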