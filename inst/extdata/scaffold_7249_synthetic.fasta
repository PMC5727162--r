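>synthetic_scaffold_7249nt_stand_in_for_M13mp18
CATTCATAACCTCGTGCCAACTAGCGCGGTAGCCCTCTAACCATCACATTGTGTGCCTCCCCTTCGCAAAGTCTTGAACC
GGGACGACGTAAACCGCTTGCCCGTGGAACAATCCCCATGTGAACTACATATCTATGCGCGCAGTTGAGGGTTCGAAAGT
TGTTGAAGTGCGTAGACTCCTGCCCCGATCTCGTCAGGTGCCGATTGAGATTCCACGACAAATCCGCTTCATTCGGCTAC
CTCGCACGAATGTTTTCACCTTTTTTTTGAACCGGTTCAACCAATCATAGTAGTACGGCTAGTCCTGATTTGACCCGCAT
TTAATTCGCCACTGCACTAAGTGTAGGTAGGATCGAGTCTGGAAATCTGATCAGCCCTAACGTGTTCAGCAGAGAGGCCA
ATTTTTAAGCCCCCACGCCCGAGGGTGGTGATGAAAGTAACTTAACGTTAGTCGCTGCGCGCGGGGCATCTATATCGTAC
ACTGCTCACATCCTGAGGGGTAACCAGAATCAACGCAATACATTAAATGTGACCTGTTGAATTGTCTATCAATCGGACGG
CCCAATTACACAACGAGCGCCCCTAAGTGATAGAAGTAATCGTCTTGTGGTCGGAGCAGCAGCGCCTACACAGGGAAGTT
AATAGACCGTGTGCTGTAGTTTTCGAATGCCTTCGATATACGTAGTTGCCCTGTACCAGGAAACACTAGATGTTCCAGCA
GTATGTGCGTAGGAGTGAATGGGCTATACTTAGACCGCGGTAGTTGTAAGTATACGCGAAAACTGGATACGAGCTGCTAC
CGCCTTCGGGAATTGCCCCAAGCACGCCGGACCGTTAAGATCTGTCCAGTCTGCGTAGATACCCCGTCCCCCTGTCACCT
GGAACCTTGAGCGTCGTTCCTTCGAAATTCCCGTCATTTAAAGCCGGTATAATCACAGAATAGTAAAGGAGGGCTCACGT
GAATATCCTTAATCAATTGCGCCGGAATCAGCCACATAGGAGCGGATCTTCCTTCCAAAACCTTGGGACACGTGGGGTGA
CCAACGCTAAGAATATTCACGTGGGTACCCCCGTCCACAGATAATGGAAACATGTGAATCGACTTATACTGGGTCTCACT
CCCCCGGCGACACACCCTTTTATACTTTCGCTGGACCCTGAGTCGGCGTTGAGATTGCTCCTGACCAAGTCCACATCGAG
ATCTCCTGAACATTTGCTCGGGGAGAGGTGCGCCTGTATTACCGGTATTGGAGACAGTTGGGACGTATAAGATTAAAGAG
AAAGTAAACCGACTGGAGTCGAGGGCACACAACTCGAGATATTGTTATTTTTAATGGCGGGGCTTTCGCAATACTGTAAA
CAATCCGGACTTAGATGTTCCGTTAGGGAAGCAATTCTTTTGTGATAAGTACGGATACAGTAGCGACGCTAGGCTAGAAG
TAAAGGTAAGGCAGGCAATCTTCGTCTTGGGGGCATATAGACCCGCGGCTTGTCACAATTGACATTCGCGCAAGTTGATC
ATTTCGGTAATCAACTCCTCAATTTGAAACCAGCTGCAGTATGTGTTTTCCAGACACTACTGTCTTGGCGGGTAACATAC
TAGACTCCGGTTTGTCACCGTACTACACACCTTGCTTGGAGTGCCAGGATCTCCGGGTGAGTCCAAAGGTTGAGATCGAT
AAAGTTCCAACGGGAGAAGAGGACGTAGGGTAGATGGCACAGAGCACCTCGTATTGTCCTGCCCTGTTACGAAGGTACAA
TGCCGGCAGGCCGTGACCTTCACATCCTTGGAAGCTAGTACTTACGAGAACACGCGGGTAGTTACGATCACTCCCACCAG
TACGGCTTCTAGGTACTATTCGGCCGGAAATAGCGTCTTTGGTAGTATACATTCGCGTACAGCATGGGTCGTGCTGGAGA
ACAGCCACGCGATTGAACACGGCGGGTATCGCTCGATGTAGCCAATAAGCGCCATGGGGGAGGCTCTCTTGTATGATGAT
CGGGCAGCACCCCAACCAATCCCGCCAATCTCCTCTTCAGATAACGCCGTCCTACGTTGCAGCGAAATATAGGTTGAAGC
GGATGAGATCTGAGTTGCGCGATGAAAACGCCCGGGCAAAGCTGCCCAATTTAGTCGGCTTCCAAACCTGGGGACATATT
ACAGAGCGTCCGGCCTTTCTTGGAGCTCGGTCCCTCGGTGAGAGCAGTGAAACGGAATGTCCAAGAGCCCAGCCAATGCC
GGTTGCGCGCCCGGTAAGAAGGCATACGCCGTGACGGCAGCCACAGCATGCCAAGGGGGCCCGGTCAATAGGATATTATT
GACCTCTAGTAGCAGTGTCCTAGATTACTTTTGTATTGTCGAGAAGCGGCATTTTTTATATGGTCGAAGGGGTAGATTGC
GAAGGTCACTAACGTATTACCGAAAGTCAGGCACTTCGTAGAATGCTCACCATGGTGCGTCCGTTAGGTAGTTCGTCAAG
GCCCGTCAGGTTGCCGCATTGCAGGAGTGCGCACGTCCGACTCAGGCTGGCACTAGATATGTCAAGGCCCGCCCTAGCCT
TGATAATTGCGGTCCTTTAGTGTCTCGATCGGATTTAATCCTACTCTGCTTGGGGTAGTTGAAGCCAGAGAAGTATTCGA
ATACGAAGGGGCCTACTCGGCCTTACTCCTTAAAGGTCTATTAAGTTTTGCCAAGGAAGATTTAACATCCGAGATCCATC
CGTAAAGCGGAATAAGAGGCTAATCGCGTCGTGGGAACGGTTATCCCATGACGAACGGACTCATAGAACATTATTAGTCG
ACTTTTCGACATTGAGCGGTTCCGAGAAAGATCGCACGTAATGGAAATTGACTGATATGATCCAATAGGGTGCGTGCATG
ATGTGTGCAGTGTTATATCTCATATCATTATGAAGTGTGCTTACGTTTGGGGCCATTCCTTGATTCACAGATAAGTGAGT
TAGTACGGCAACGAAAGGGGTGTTGGCACGCAGTACAAACCCGTCACAAACCCGGATGGACCCGGCTGGAGACTCATGAA
CTCGATCGGCTTTAGTCTCGTTTTTACCCGACTTTAAGTATGTTAGCTTGTAGCAAAGGACGTCTGCTATATAGAGTCTC
CGGTATACCCGGTTAGAAGTCCGGGGAAATTAAATTTCGGCCTGCGCGCGATCAGTATTGAGGAGTGCCGTTGACCGGCT
GGACCCAACGAAGATAGTGCTGTTGCATCGGTCCTATTCTCAGTCGTAGTGAGCACAGCTTTGGCCGCTCTTAGACTCAT
AAGGGTGTTGTGAATCTTAGAGCGCCTGGTACGTCCAAGTCGGGCGAAGTAGAGTTAGGTAGTTACGGCTGTTCTCTGTC
GTGTCTGTTCAGATGGGGATCCTGGCAAAGGGCTCTTATAGCGCTTATATCAGGGATGTCCCGTCCCGAGCAGCCTGCTA
GCACCTCCATCGATCGACACGATGCGCGGAAGATCGCCGTCAAAAAATCGACTCATTCCGCAAGTGCCAGTAGCCTAAAT
CAACCGATTCGTTCATCGTGGAAGAAGGGCCCAATGTAGATGGACGAACACGGGAGCACTTTAACTTCATTCGTCGGATT
AAGTGCCCTCGGGTGAAAGGCAGTTAACACAACGTGTAGGGCTAAGTCACTTAAATTGTGCGGCTTGTTGGAATTACCCT
GGAACATCTGTGTGCCCGGCATTTCTTAATCTGCTACATTTGTACAGGGACGTCAAATCAAGGCTGTGTATTACTTGATA
CTATTTAAGACACACATCATTGACGTACTTCGTTAGATTACACTGTGGGGTGCAAATATTTCTCCCTCTGTCCCAGAGAT
GAGGTGCTTTGTCCACGGCTCAAGGTGAAGGGTGCCCCACAATATTACCTGACAGTCGTCATGCGGCTTGTTTACTCGAT
ACCTCGATCATTCCTAGTGTGCGTAGGAACGGATGTGTAAGTGTAGAGCTAACCTGCCTGCAGCTGTAAATTCATGCGCA
CGTCGGCATTCAGTCCTTTTCCGCGCAGTCGTCTGGCATTGCCTGATTGCGACACCAGATTCACGGCGGCGGACGTTGAC
CTTTCTTCATATACTCAGTGTCTCAAGCATTCTTGATTAGAACCCCCTGTGAGGCTGCCATGAATATCTCTCAAGCTGCG
GGCTGCGCGGCTTACCCAATGTGTCAGGCAATAATCGAGTAGCCTCGGAGATATGCACACACCAGCAGGCAGATGCCATT
TGAGGATCGTCCAGCAAGATTACACGCCCGTTGGAAATACCGATGTGCTTTATGCCAACTACGGACGCCGCAATACACGG
CGTGCAACGAGTTACAAGATGAGCAACATGAGGCTCTCGACCAACTGGGAGATACCAGGGCCAACGGACCGCGACTCACA
CGTCCGTAGGGGCCCCTAGACCAAGCTACACCGGAAGCGCCTCACTACGCCGTCCGGTACGAGACTGTATGGACGTGGTG
GTGGACGCACCTCCGTCCTCACGACCTCTGAGTCTTGGTCCTGATTAGCTGAATTCCCTGCACCCATTTTACTTATAGTT
CATTGCTCAGTGCGGTGACACGGTGAAGCTAATCAGCTACTTGATGTGCCCTAGGCCCTAACCTTACATATGGTTCTCAG
ATGGCTTGAAAGGTGCATGGCCTTAGTCGTTGATTAGACAAGACGGGCTAGGGGCCGTTGGCGAGCAGACTGTGAACTCT
AGTGTAAATAAACTGGTACAACTCGTCAGCGTGTTTGTCCCGAGACCGGGATCGAGGGCATGTGCTGAGATCAAAATCTA
GAAATGGCTTAAGGTAGTGTTAAGACCTGTTTATATTTCTTGTAGCAGGTGACCAGATCAGGTCCTCCTAGACACGTGGT
AAAACCAACGCCATCCCTCCAGTAAGCGCCATAAGGCAGTACACGTATCTGTCTAAAATGACTAGGAAGTGCGTAGTTTT
GAGTATTTCCACCCACATCGCTACTTCACAGTCAGTGGAGTACAGCTTAAACAACTTTCGTATCACAGAGAACAAGAGAT
TATGTCACCGTCTACATTCACGATTAATGCTTTGTTTGGTTTTTGGTGTCGAACCTTGTTGGCGGTGTTCCGTACTTTGT
AGGGGGAAAGAAAGGAGAACCATCCCCTACCGACGAACGTCGTTTTCAGGGAAGAAACTCTGCGTCGCTCCCCTAATGCC
CATTGTTTGGAGCGCCTCTTTATCTGCCGCTGCGGAAAACACGGAACAACCTTCGCTCAACCTAGTTCAACTATTACCCC
GTTAAGAAAATACAGTTCTGCTCGCCTTTGCCCACCTCTCCCGGCCGATTAGGGCTATCAGCCCAGATTGTGACCCAAGT
AAGCTATTATGTGCGTGTAAGAGAAAAAATCCCACGACTAAGTTGCGCATTCCGTCGTGATCGGCCTCCTGTAATATACG
TCCACAAGCTAATATCCAGGGACTTTCGAGCACAGGTGCCATAGATGTGCCTGCAAAACGGATCATGTCAGAGTTAACCG
TTTACATGGCCTCTGCAGGAGCCACTCCGTGCGGAGCTGTATGAGTCGGCATGGCCCAGACAGATTACGGCACCACAGTC
TCTATTACGGACTTCAGGACCCGAGTAGAGATATTTCTGTTCGTGACGACCAGCTCACCTCGTAAGGGAATCATCCGAAC
GGTTATGTATGTTCCCAGATTGAATTAAGCACGGGAAGAAGACATGAGAGCTTCGCTTACTGGTACGAAGCGTTGAGCAC
GCGAAGCCGCACGGTACTTAAGATTGCTGCGCTCAGCTGCATTCGTGGCGTATTGAGAAATTAGTCCAGTATCGTCTGAG
CCAACCGCCCTCAATTATGGAAAACTTTCTTTAGTCCGAATCTTATGCGGATGCCTTGACCAGACCATACCTTCTATTGA
CTCGTGCTACATAGGCTGCACTTCAGGATTAGGCTATGTAGAAATGACCTCTTGCGACCATTTGATTCACAAGTTCCCAG
GCAGCAGTTAGCTTCTCTCTTGGAGCCCGACCAGGGCTCCACAGCAACGAGTTCGGGATGCGACAGGACTGAGCATACGG
TCGGGAATCAACTCAGACGAAGAGCCTGACAGTTCAACCATGCACTGCTGCGGCTTAAGGGAGTGGACTGCTTGGGTAAT
CTAGTGCGTAGCATGTAATAGTTACTTTTTTAGTACCTTAAATCAAAAACTGCGAGGTATTGCCAACCCCTCCCCCCTAC
CCGATTGAGCGGGTTCGCTTTTTTCGCACGTTGTACGTAGGAAGAGTTGCCCATCAACCAGGCGTTGGACATCCTCGGTC
GTCAAGCGGATTGAAGGGGCATCAAATCCTACGAGTCTGAGTTTTAGGTTTGGGTCTTCGTGTTATTGGCTGGCAGGTGA
GCTCATATCGTTAATGGCGCTAGCAATTAGCTACTGGGCATCGACGCGTAGCTCTGATCACCTCCAGGAACGGAACTACC
CCGGGATGCACGCATGTTAACGCCGTCGAGTACGCACATTCGGTAGGAAGGTTCGTACCAAATAGATCTCTGGTTACTCG
CCCCCCGTCAAATCAACCGTTCCTGATTCTCGTGAGTCCAGTTCCTCTTCCACCCGTCATCTGAGCGATATTGATTTAGT
GGATCTACATTGGCTGCCCCCCCTGCTTCGTCGTGTCGCGTGAATTGCCCGTGGGAACTGAGACTATCTTATAGAGCGAC
GGTGATCCGGTGGTGACTGGAAGGTAAACGCAGACCTCAAACTCGGGCAGGGCACACCCAGAACCATCCCAGATATGTAA
AAGAGTGCCGTGAGTGGTGCTGCAAAGCGCTCATGCCACACCAGTTACGAATCTCCGAAAATCGCATAAGCCAAGCGACT
TATACGCGACGTCCCTCTAGCCGTGCGACATGGGCTGGTACTTCTAGTAGCAATTGTCACAAGTAAGGGCTCCAGCACGG
AAACCGGCCGGCAGAACGCGCTGTGCCGATTTAAAGTCCATGTGGAGCTGTCCTGCAGTGTAGCGATATTAAAGAGCTAG
CTTCCCTCTTAACCGTTACACCAAGCGAAGATCAATAGATCCTAGTATCTCGAGTGGTCTCGCAGTTAAGAACAGACTAA
TGGCAGATGATTTGATAACGATGGCACGATTTGACCTCGGTCGGCAACTATAAGCGTTTTTTGCAATGTCGCCCACCCTG
GACCTAGGAGAAATGCGCTGGAATAAGACGTCCGCTCGCCGTGTGCCTA
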