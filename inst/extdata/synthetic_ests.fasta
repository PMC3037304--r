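>est_01
GTTAGACTGTGTCCACGGTGTACCTAACGTCGACTCAATATTAGTCTCCCTAGTATTCCTAAGCCTCATC
GGTCGCCGGTAGGTGCGGAGCCAGGGGGGAAGTGAGAGAGTGCCGTCTGCATGTCGTTAAGATCTGTCGT
AGCGTATCAATTTGAAATGTGTTTCGAAGAGTACGCGTATGTGGAGGAGTTATAGTGGGGCCTCACAGCC
TAGAGCAGTCACTCCGGACGTAAGCGTTTCGTCCCCAGGTATGCACTATTAGGGGCGAGAGTAGAGAGAG
AGAGAGAGAGAGAGAGGTCCATCACTCTATTTTCCTGTAGAACACGCACAATTTATTTGAATAGATACGC
TTAACGTCCGCACATAGGCATATATCTGAGGGGCAGTGATGCTGAGCCAGCTCGGTTCCACGGTAGCTCA
CCAGAGCCTATCTTTCTCTTCAAAGCTTCTGCACTGTACGTAGCCATCTCCTTTCAACCATGGGCCTCGT
ATCGAGTACAGACACAATAATCCTTCCGTAACTCGGATAATAGTAATAATCTGCACCGCTTTGTGAAAAA
AAAAAAAAAA
>est_02
AGAATTCAGATTGCTGCAACTGTCGTCGATCACTCGACGCATCTGTGTTTGCACTGTGATCTAAAAAGTC
TCTTAGTGGAAATTAGATTTGTTCGGCGGTTCAGTGCGGTCCGGCACGAGGCTATTGCGTGGGCCAAGTG
CCAGGAGGCATTCCTATCAAGCCCTGTGAGGATCTCGTCACCTTTACGGTCGAATCGGTTCGATCTCACA
GGGACGGGTCTTAGAGAGAGAGAGAGAGAGAGAGAGTACCTAATCCACAACTCTGCGACCGATCTGCTGT
CACCGGGAGCCGTTCAACCGTCATCAGCCGTATACTCGCATGTCCACCCTATCAAGAAAACGAAGGTGTG
TCTATTTTCAGCTCTGTGAAGATTGTATGCAAAACCATTGACCGCAGCTTGAGCTGACACTACGCGAGGC
TCTGTTGTGATCCGGCGACTTATTTCTCGCGTCAACACATTGTCGTTAGA
>est_03
ACGCGGGTTATGCTTATCTCAACGTAAGCCTGCAGATAGGACGACGCGGAGATACATTGACCGTGTTTAA
GAGGCTTTGAAGCGCTGCTAGTTGATGCTGCGATCGGCTGACTGTCCGGAGAATGGGCTCCCCCTACCTC
CACATCCAGTTTACGCTCAGAAAGATACGGATGATGTAGCTAACTGCTCGGACGTTGCGGCGGAGTCGTA
GGTGTTAGCAAAGTTCTTGGATGTGGAATGTTCCTGTGCAGGCACAGATATCATGGTGTGAGCCTATACA
CAGAGAGAGAGAGAGAGAGAGAGAGTAAAGGATTGTCAATGGTCTTACGTACAATCCTCAGGTGACTGCT
GGATCCGAGTAATCGACGTACGGCAAAAAATAGGTAAGATCACTCCTTCGAACTTGGTTAAAGTGTGCAT
ATCTTCCGACTCATGCTCATTCAAACGCTGTCGTCGGCACACCGGGCTTTGACTGACGAATGTGAGTCCG
TATCTAGTTGGACCAGCACTAACTAGGGGTCGCTTGGCAGTCGTGCTTACACAAAAGTGCAAGCATTATA
AAAAAAAAAAAAAA
>est_04
TTGACTGAGCCAGCAGCCGAAGTTCCCTATAAGGCGCGCTCAGGATGACCCTCTGGCCAAGCAGGATACA
CGGCGATATCAACAAATCCCCAACTAGGTACAGTAAGAGCCCATTTCACCCATTTGGTCTCAGCCCACCC
CCAATTCAGGCGAGAATCAGAGGGTGGGGGTTGCAACAGAGAGAGAGAGAGAGAGAGAGAGGCATCATCC
CTTATTGTACCCCAGGTACGAGGCCCCGCCTCCATCCGGCTGATGAACCTTTGGATCGAAGATTGCTAGT
TTTTGCGGACCCGGTATCATTTAAAGCGGCTCACCCCCAAACGACTCCAGCTGTTCGCGGATGATAGGTT
GATTGGAAACGCGTCTCTCGTTAAAAAAAAAAAAAAA
>est_05
TTTGTAGGTCAATGCATTAGTTGCTTGAGAAGAGAACGATTGGCATAGAGCGCAGAGGCCCCATTTGCAT
GGTTTGTCTATATTGACAGCTATCTGCTAAACGTAATTCCTACTGAGGCAATTTCGGATATCGGAAAGGC
TCTTAGTGAGAGAGACTAGATTTTCTCAAGACATCTATTGCAGTGCAGCAGCAGCAGCAGCAGCAGCAAT
GATCGCGATGAAGGCAGGAGCTCCTGTTTATCGAAGCGTACTTACACGCCGGAGATCCCCTGCGCGCGTA
AGACACGTCAGTTCAGCCACGTAAAACCTTGTAAATAATCAACGAGGATACTAACGTTCCGTAAGATGCT
CCCCATCCTTATCACAAATGGACCGCGCTTTTGAGAGTGGCTGT
>est_06
ACAGTCTGTCGCACCATGCAAACCCGCGTCCAATGCCGTCTGTATCCTGGACGCACTAGTGTCTATTGTG
GCGGAGCCTTTCCTTGCACTATCATTCACGGGCGACTTATGCTGCTTGCCATGCAACGGCTGCAAGAGAT
AAGGATCGATGTTTCTTGTTTTTTCGGTGGGTCCGAATTGGCGGTTATGGCGCTTACGCGACCGGCCGCA
CAGGCGCAGCAGCAGCAGCAGCAGCAGCATATCATCCGGTACGGCCGGGAAGTTGGACTCATACTCCGGC
ATCGCTTATCCATGAGTGGGTGGCTGTTTGACGTCCACATTGGTTCCGTACGTAACGCTGGAGCTGAAAT
CGGGGAAATTTTCTTTTTTTATGTAATACCGGAAAACCCTGGAATGCGGAGGAGACGCACATAGCATGCT
ACATCATTCAAGGTTCACGCACGTTAAAAAAAAAAAAAAA
>est_07
GCGACTAAAAGCAGTAGTGGAGGCAAAAACTATATCCACGTATCCTATCGTTGCGGTCCTAGGGCACGAG
TGTGGAGACACGTAGTTCACGCCCGTAAGTCGACCAGGCAGCTGTCCGCACGATCCTGAGTCGTACGTAT
AAAATATATTCCAAAAGTGCATGGGTATCCTATTATAGTCAATCAAACATACACCCCTCACTCAGTCCAT
CCCTGCAGCAGCAGCAGCAGCAGCAGCAACCCGGTAGGAATACTGCTGATCAGTGTGACTCCCCTCTCGC
CTTTTCTTCCAACCCTCCTGGCCCAAGGGCAGCAATTGAACTAATCTACTTGCATTCACTAGGCGTACTT
GTACCGCCGATACGGACATGCGTCATGGATCAAATTGTTACGCCAGTCGGATTAATATAACCAACTTTAG
CCGAGAAAAAAAAAAAAAAA
>est_08
GCTCACCAGGTTCGTAAGGATGTCTGTTGGCGAGCTGAGATCGTTTGCTGTCAGGTTCTCGGGAATTTCT
GAGGTATATCAGCACCGGGCAAACGTCCATTTGTAGTCAAGATGCTCTAAAAAACATTCTTTCCACACTC
ATCCGTACTGCCGGGCGAAAATTCTTACTGAGTTTCATCGTTGGGCGCACTTGCCAAACTTCACATGGCC
CCTGTCGCCACTAAGAAGAAGAAGAAGAAGAAGCAGGTCATTGCTCTCTCTTATTCAAGTCAGAGGTAGT
TTCACATTGTATGGGAGAGCTGATTAGAGAAAATATCGGGTATATAGATATGTCTCCGAGCGCGGGTCTA
TGCGGCCCATAATGAATTGCAAGAGCACCTTTGGCGAGCTTTGTTTCGATGAGAGCGATCGGAACTTAAG
ATACTTCTCATACTCCCTCCATAAAAAAAAAAAAAAA
>est_09
GATGATACGTCCTAGTGCCGGGCTGTCGAGATGTCCGGCTAGGCTACTATTTAAAATCACGGAAGTAAAG
CCTCCATATCTCGAGCGCGCACCGTATGGCGTACTCAATGTCAAACAGGTTCACGGTGGTAGCCACAGAT
TATAAGGCAAAAAGCTACCGTTGAGTCTTCCACCACAATCTGTAGACCGGTCATGCCGTACTGTCGCGTT
ACCCGGAGCAAGGCGTCCTAGCGAGCAACGACGCGGTAAGGGGAAAGAAGAAGAAGAAGAAGAAGCGGGA
GAGTTTTTCCGCCATTGGCATCCGACCTACGAGTCACTTGCAAGCGCATAGGTGTTGCACCTGTCACGGT
CAACAGTCCAGGTCGTAGGCGTTATCTTGCACTGTTCCCTCTCAAAAAATGGCACGCAACCCCGGTCACT
ATCAGCGAAGGGTGTTGCCGAGGCTACTTAATACCTTTGGGGCGTCTCACCGACGTATTGTCTGATGTAT
CTCGTCTTAAAAAAAAAAAAAAA
>est_10
GATCGCCTCACTTGCCTTGCGTTGGTTGAAACCCTATGCCGGAAAGTCTCGCTCTTTGACGGCTTAGTCT
CTGAATTGTCTTCGCATTGACACAGTAGCATCGAAACACTCGCGGTCACAATTTAGGACGTCGATCCATA
CGTAGTAAGTTTATTGTTCCTACAAGGTTTCATCTTGGGGCTACCATACTCCACGGGTATAATGGCGGGG
GAATGCCAAGTTCTCCGGTTCGGACGACGGGGCGGGAAAGAAGAAGAAGAAGAAGAAGTCAGCGACGTAC
GACGCGAGTTGGTTATAGAGTTGTATCAATTCTACCTTATGGTCAGAGCGCGGGTCCACAGGTGGGGTAT
CCTAATTGTTCGATAGGAACAAATGGTCCTTTCACGTTTCGCTGAGAGTGGTGAGCGGGCGGTTAGGCGC
ATTACCCATCCCGAAAGGACCTTCATCACGGGTCTGCACCGTACTCCAACAAGCGCATGTGCCCGCCAGG
CAAACTAACGCAGAACCATCAAAAAAAAAAAAAAA
>est_11
TTATGACCCATCTTCCCGAGAATCATCTTATACCGATAACTAGCAGGTCTCTGACGGCAATGACCAAGAT
AGCAAAAGTGCAAATTTGGATCACACCACAATGATAGCCTACCAGAGTTGTTACTTAAGCGCCCAAATTC
TCCGCATTTCAATCCGGACAGCTAGTTGACTGTGGCTTGATACCAGGCATGTCAGCGCCCGATTGATGTC
CAAGAGGACCTGTTGAACTCTCTCTCTCTCTCTCTCTCTTGTCCCATGCGTTAGTACCAGTACACGCTTC
AATGCCGGCCCGTGAAATACAAAAGTGTAAGTAAGATGAACCGTTGGATTGAGTATATTAGGGATGCCAA
GTAGGATTCCGTCGCCATATCTTCTGCGGCCGCCCTACAGATTCGAATGCAACATCTGCCTTTCGAGCCG
TTGAAGGGTAAATAATGTACCCCAGTAAAAATATTCTTTGCCTGTCTAAAAAAAAAAAAAAA
>est_12
ACCCTAGTAGGGACACGTATGACGCTACCGGTAAGACGTCCGCAAATTTACTGAACGGGTTTGAAGCTTA
ACGCCCCTGGCGGCCTCGCCGAATTGCGGATGAAAGTCCCCAAGACCTGTTCAACACAGAGCCGTATCTT
TCATAACGGTTCGGGTTAACAGGCTTACCCTTCGCCTGAACGGACTCTCTCTCTCTCTCTCTCTCTAGCT
AATAAGACTTTTTTTCTTGAGGGAGTCGAGAGGACTCAGTCCCCCAATAAGTTGGGCGACTACCAATATT
CGTCGGGTGAGACAGAGTTACCATCTGTAGAAATTGTAGGCGCATGCGCAGACCAGTTGTCGCTGCTGTC
AGCTGAGTATTGTAGAAAAAAAAAAAAAAA
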