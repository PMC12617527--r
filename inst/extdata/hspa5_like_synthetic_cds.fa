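>HSPA5_LIKE_SYNTHETIC|SYN1
ATGCGGCCAATTGGGTCTTCCCAATCCTTTTCGCGGTATCGGAATGCGTCCGAGTCCTATGTCGGCGATGCGACTTCTCC
CCCTTCCCGAATACCCGGACAAGTAAATATCTCCACTCTCTCCGGGAAGAATGAAGCTTTCTTCGGCCTCGTCAAGCTGT
CTCCAGACTTGCAGTCTTATCGACTGTGTAGACTGGGCGCAGATCGGGATTTTGATCCTAAAAAGTATACAGGGTGTACG
GCTTCGCAGCCGTTACCGCGACCCCGCGCTTCTCCCACTAAACAAATAGACCGGTCTTTGAACTGTTATTGCGCCTATAT
CTCCACAATTTCCGCGAGAGATGGGAAAAATTCAGCACCAAAATCCAAACACATCATTTTAGCAGTGGGATCCAATCGAG
GTGAATGGGGAGCGGTATTCCTAACCGCGCCAGTATCTGGTAGCTCTTGTACCCGGTCTAATGTCCGGTACACTAGTGTG
CCTGACGTGTCATCCTGTGGTGATCTATCCTCCACTGCCCATTGTGAAATTTCCCCGCGGAACGTATCCCGTTCCCAATC
TCCGGCCTTGTACTTACTACAGGGTTACTTCAGGAATTCCGGAGCTGGATATTTGACTTCTCACGTTTCGTCTCAGACTG
ATGCCCAGGGGGGATCTCCCTTGTATTCCTTTCTACTAGGTATATCCATTTACCACAGAGGGGTAACTCTAGGACCAGGC
TCCTCTGATCCCATAAGACTTGGGCAGCGTTCTTCCTACTGTTCTTGCTCTAACCTCTTCGTATACAAGCATATGCGCAG
ATTCAGTGCTCTCGTCCTTGCGCGCGGCAGACAGTCTTCTTCCCTTTTGGTTTCCTCCTGCCTGATGGTCTGGCCTATGA
CCTACTCTTGCTCCTCCCACAACTCTCCGGGGTATCGTTCGCGTTCCGCTAGAAAGGTGTTATCTTTGAGCGGTAAATTA
TCTGCTAGGGCTATGACTAATCCTATTGAACCCTCTGCCTCAGAACTAGTCACCCGCACTTCGTTGCGTGTACGCCACCC
TTTTTCCGAGAAAAGATATAATCGTCCAAGGGCCGGTACCAGGCCATCTTTTGCTCCGCCTAATGCCAGCCCTCTTATAG
TGACTTTGGCGGCCTTGAGGGTCGTCTCCTCCTACTCACAGTCTTCCATCGTAGTGAAAGAGGTTGTCTCCAGCGGGACA
GGGTTACTGCGTGATTCTTTTTCCTCTCCTCATCGTGTCTTAAGCTCTTCCCAGGTGTTTCGATACAGAGTCAAATCCTT
CTCTTCCTCTAGCCGCGCAATCATTAACAAACTGTCTTGCAGCGCGAAGGTCTCCTTGAAATCTTACACCCGATCAAGTA
TCGATGACCGGATCCTAAGATCTATACGATATCCTTCTTACATATCCGGTCACGCACGGAAAAGTACGTTCACCTACTTG
AGAAAATCTTACAGGGCCGCGACACGCTGGCGTTTCCTTGGGACCGAACCGACCGAATCCTCTCCGATCTCTTCCCCCCA
CGCCCGCTATTCTGCGACCGAGATAGAGCAATACATGGACATAGCCGTAAACGCCTGGATGCCCGTTATGATTTCTTATT
CGATTCAGAAGCTAATCATATTGACGTTGATTGAACCACGGTCTAGGAGGATTTCCCATGTACGGAATCAATCCTTGAGC
GGGGGTACTAATTCTCTACCGGGGTCTCTCCCATTGTTCGAACCCATGCTTCTTGAGGAATCCCTTGCATCCGGGAAGTC
TAAACTCAGATCTTTCACCCTGCACGACCAACTCGTCTCCTACTTGTTCGTTCTCGCAAGGTACTCCAACCTAACCTGCG
GGATTATGAAGCTAGGTCCGGCGGGGTCCGTCTTTCTCCCCAGGTTCGAGACGGCCGAAGAAGCGCCTTCAAATTCTTTT
GGAGTTATATCCTCCCGGCTCTATATAGTCGACCGGAAGTAA
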