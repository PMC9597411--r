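>toyRE01_len60
TCTGCCTGGAAGGAAATACGTTTAATCTCTTAATTGCGACCCTGCAATCCGAAAATCCTG
>toyRE02_len91
ATCTTGTCAAATGGCTTTGTCGGTAAGTCACTCGCCAGACAGTGGTTGGCTTCGGTCCCCCAAGAAATCATTTGGAAAGGCAGTGGGACGG
>toyRE03_len122
CAGACTTGGAGGGTCCTAGGGTATGGACAGAAGAACGACCTAAAATGGGTGGGCGCCACGGAATACGTGCCAGCGGGGTACTCTAACATGCGTTGCGGAAAATTCTACAGATTGCCGCCTCC
>toyRE04_len153
GACTCAATCCGATAACCCCATATCTGTTCGAAAACAAGAACACTATGAGTCAGCGCTACAACCGATGGGGACTGGGACTTGCCCGATGAAAGTATCCCTTCTAAAGCACTAAGTAGGACACTTAGGTCTCACTCGCTCGGTAAGCGCCTAAGG
>toyRE05_len184
TCCCCGCGGGTTTGGCCTGTTCGCCGGTTTTAGGCGACTAAGGGATAACAACTGAGTTAGCCGATGGGGACGCCCGAAGCCAAGACTGATGGCTTCATGGTTAAAGGACGGCACGATAAAAAAGGCGGGAGGAGCCCCGTGATGCCGGATACGGCTTTGCCTGCCTATACGCGGCGGTGCGTAA
>toyRE06_len215
TAGCTATTATCTTACTCGGTACGACGCATCGATGTCAGCTGTGAGTCATGACCTTGGCACCCTGACTTGTAACCTAGTGGGTGCTCAAATACGAAAATGGGGCCATGAGAGTACTGCTCGCACTTAGTGGCGACTACAGCTTCTATAACCGAAAAAAACATCCGTGTCATGACTTCCTCCTCATTGTACAGACACAGTCGCATTGAACCGGTGTC
>toyRE07_len245
GTTGCTTCCGGCCTCTGCCCAGGACAACGACAAGGTGGGCAGTCAACCATGCGGCTACAGCCTTCCGTGCCGTAGTGGCTGAGTATGGCACGCATGCTCAATCAGGAAATTTACTGCGCTTCTCGCACTAGCAACAGGGCACCGGTTCAACAACCGTAATAGACCCCGGGCTTTCCTGCTGGTGCGATATGTTCTACCGATGGTGCCCTCTGTTCTGGCACACTAATAGTTTGTCAGTGCGGTTG
>toyRE08_len276
GTAGCAGCGGGTCCTCCCTTTTGGGAATGGGGTGTTCGGACGGGAGGTGCCGGGTAGATCCATGCCTCTTTTACGTGTTCATGTCAATATATATGCTGCCCTGAGAAGAGTTAAACTAAATTACCGTACGAGATATTATCAGGATAGCCTGAGAACTCAGCCTTTGCGACCCGCATCCAAGAGTTCATAATGACCGGGGCGACCCCTCTTTGAAAATTCTTAGCACTACTATAGCCCAATGATTACATTTCGATACAGATTTCACCAAATTGATCG
>toyRE09_len307
TCGACATAACCGTCCATAGTAGAATACGCACAGCTGTTAATACCCAGTGAGAAGTAAATGCCATTGTGTGCATATCTTCAGAGGGACATAGCCGCATAATCGTCCAAGACCGAGCGTTCACGAGTTAATCAAAAACGGTCGTGGCCAGGCAAGCAAGCGTTCCTCTGGCCTCATCTAAAACAGGCCACACACTCCGTCCGCCCCGTTAAATTTGCGTCGGGAAAGCCGGTAATATTCGGCGCCGAGATCAGCTATTACGCGCACGGGTCTGGATTGGGGGCTAGATGCTTTTTACTGAGCTGGGTCA
>toyRE10_len338
TAACACACGTCGACGGATGAGGACACCCAATGCATTCTCCATGGCACCCTTGCATCCTATTGTCTAGAAAATGACCACTCACGCTAAGTACTAGGGGAAAGACAGATCGACGCCGCGTTGTGAAAGACGCAAGATCGTCACTGCTCGCAACTATCGAATTCGTTCTTTTTCTTCAACCTACAAGGCAAAACGAGTCGGCTGGCGGAAGCAAAATGGAGCAAGTACAACTGCGCAGTCCGACCACAGTTGTTGTGGCTCCCCTTAAGACACCCACAACTAAATAATCTAGTAACGCTTCCTGAGTAACTATCGTGTCCCTAGTGGCGAAAGCAATATCC
>toyRE11_len369
CCAGAGCGCGACCCGGTACCAATATAACACGTGACAAGAAGAAGCTAACTTCGGAGCATCCGAGGCGCCTAAAAACCCAGCAACACTGTTTGCCTTAGAGTCAAAACATCCAACGCAAGAGCGTTTGAGTGTTAATGTGTCTCCATTCCGTCACGGTAAGCCGTCAACAGCACATGGAGTGGACTACTTGTACTCCGTGTGAATAGCCCGTTTCCTCCCATTCGAGAGGGACAAGTGAAATTCTAGCTCGGAGAGGTCAATGGGCTACCAGGGGGCCCGAAGATTGTTTCGGGGCTGCCGTCGCCGATCCCACAGGTCATATACTGCCCAATTGCAATGCTCTGCTTCAGCATAACTACGGGTATGGTC
>toyRE12_len400
TGAGCTATGGTCGAAAATGCTAAAGCTACCCCATAGCGAGACTGAAAGTCAGTCAATTAGGTTATTCGGTTTCTTCAGTCTGGGGCTTCGCTATATATTGATAAACCTGATTCCACAAAATCATTTTGTAAACGATACTACAGTGCTGCGGCCGTCCATCGAAGTATTTACAGTGTGCGGGATAGCAGGCACCCCATCTACAGAGAGTGTATCGGTTTCTCCACTAAGTGCGGGGGACTACGAATTTCCCCATCAGTGCGCTCCGTGACCCTAGCGTAGTTGCGCACTTTGGCACGCCATGACGTCATTATGAACTCTTCATGTCTCTTACGGAATTTTCCGAGAATAGCGTCGACCAACCGGAGGTTTTCAGTTAGCAGCATTAGAAAGTTTACAGCCC
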