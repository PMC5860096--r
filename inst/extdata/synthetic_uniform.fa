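>synthetic_bg_1
TCAAATCTACAATACAGATCGCTTTAGCTCGCAACTCTTCTCTCTCATTTGGTGGCAACCAGTGGGCCCCCGTGAGCCGTTTAGCAATCCCATAGGGCTACCCCGCTATAGCAGGGGTATGCGAGCTAGATTTGTGTTTTGGAGCGATATATAACTCTTTGTGGGGCTACCTCGCGACGTTCCTGGGATCCGTGACCTCCGTGCCTAAGCACTGTCTGGCCGGGGAGCATTTACTCTAGGAATGTCCGTCTAGGGCAGTCCATCTCGGTGAGGCTTGCTCATACGAGAGCCCACGGGAAGCGTCAACCTGATATTTTCCTGTGAGTTGTCCTGGTCGCACACGATCACGGGCTATCGCCATTTGTTCCGACATAGCAAACAGTTCCACCTGCAGCACAGCTGTTCAGATCATCTGAACTTGTATCTCTATTACCGAACCACAACTAGGCATACAACCAAGTTCCGACCTTAACGGACCCACCGAACTTCTTCCACCAATCACAAAGCCCACTCTTACCGTATACTCTTTTGCCTGGAGTGTCGCCTAAGGTCTTTATATATCTTAACGGCCTGTGGCCTTCCTCATCGAGGGCCATATCC
>synthetic_bg_2
GACTGGCGCTACTTCCACTATGTCTAAAGATCGGAGCTATAACTTGGATCCTGGCTACCAGTCCTTGGCAATATTGGTTAAAATAGATAGTTTAGAGAGAGACCAATGCTCACGACAGTCGTAACGGTTCCAGTGCTGTAAGTCGGCATAATGTGTTTAGATTCGTGACCGGAGTTAACAAGGCAACTGGGGGCAGAGTCCCTTCATCTGTAGCTTCCACCCACGCGTGCGAAGGACAACAGGCCATTAGTGGAAGCGTGGTCCCTGCTCATGAACTTAGCCTGGGCTGTATAAAACACTAGTGAGCTTTAAAGATGACTCGCCGGTGCAAACTCCTACTCGCGCCACTGGAGGTACGCACATCCGGACATATTATGGACTTTGCTCCTAATAATTTTCTCTCTATTAACACACCCAGACCATGTAGCAAAACATGGAACTGTCCCATAGGTAATAGACTCAGTGTTAGCCACTAAAACCCCCCTTTCTTCTATACCGATCTTCATGTCGAGCAGCTGTGCCCTTTATTGGGACAGCACCTAGATATTCGCTAACGGGGAGGCCGACCGTTCGCTGCGGAACTCTCGCCTGGTCGTCAAG
>synthetic_bg_3
ATGCCTGAGTGGGGCTGAGCGTTACGGGGATTACTTCCTCGTGAGGCGATGCATTGATCAGCTACGCGTAGCATAATATATAATAGCTAGCCAAGGACAATATGCATAAGCAAACACTTTGAGGTTTTCGCTATGCCAAGCAAACTCGCCATATAACACCAAATGGCTAATTGTATTCCACGCTTGAATGCAGTTCGCAATACGTATGCGAATATATAAGCCGATAAACAACCGGCGCGTAACAGCATGATCACCGCGGAGTCTCTCCTCTTTGTACGGGCCGGTTTCGAGCAAGACCATTGAGGTACTTCACAAGGCCTTTTCCACACCACCCGGTTAGACTGAACTAGGCCTCTGGAGATTTGCTAGACCCCCTGCGTGTTGCCAGGCCCGGTTATGGGTCAAACGAATAATCGCACATTTCTATCGATGTCCTCACCCCATTGTAACCGCTACTTGTGTGGCCCGACGCCTGCCTGATGCGACAAGGAACAAAGATCCGGGATGAAGTACCGAAAAGCAATGGTATCCTTCTTGTAGTGACACTCAGTGTCACCCGTATGAGAACGCCGAACGCTCCGGATACCAACACACCCTTAT
>synthetic_bg_4
ATCTACGGATTGCCCAAAACACGGGGATTTCCATTTCTTTCTGCCATGGACCTCGAAGTAGCTTGTGTCTTAGTCACGGTGAGGTGCGGACGGGAATACGCACGTAAACTGTGTGATCCCTTTCATGTGCCAAACGCTTACTAACCAGGTAATTTTGCTGACTGAGCAAGCCACCACGCGGGTTCGAATGGTCTTAATTTTTAGGTCCAAGAAAAACATTAACGTATCTCAGGCTGGCGTTAGGTAGTGTTCCGGTTCCTAAAAGTAATACTAGCGAGCACGATTCCTAAGTGCTCGGGCTTCCTACACATAAGGCCCAAAATGGACTATACAACACTAGGGAAATACGGCCCACGATTTACTCCAATCTAGGCCATAGCCTCAGACTAGACTCAGAAATTTTCTCTCTTATACATCCCACCGGTTTCCCTTAGCTAATATGCAGAAAGAGCATTTCGATTCAGGGCTGTTATGTCCGTGCTAGCCCTCGCCAAGAGTTCCTCATATTACCGAGGACGTACCTTCCTTCACGGAAACGGACTGACCACGGTTTTGATTGAATCAATGTTCATGCGGAGGTCACCGAATCCCTAATCAACA
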