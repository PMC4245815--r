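>simg0001|exon|1
AGTCGAATAAAATGATGGGAAAATGTTAATTTTAGGGAAGGGAGATTGATCTAAGGATTCACAAAATTACATTTTAAAGG
AA
>simg0001|exon|2
AAAGGAAGATGGGAGGAGGAAAGGGGAGGTTTTAACTCTTCCGACCTCAAGAAATTGCAAACAGGGTGATATACTCGAAT
GCAT
>simg0001|intron|1
ATGCGATAGCCAAGGTCCCGATGTGTATATGTATTTCCATCCCTTAACGTCTTTGCCTACAAGGTCCACTTGACCTTTTG
TGTTATTTAATTTGAAGAACATTATATGTTTGTATTCGTTTATAAATAATTGACCCCATCATGTACTAAAGATCGGGATA
ACATAGGAAAAAGTCTATGTAGTGCGAATTACTGCTGACATGAAAAATAGGATAGAATAATAATGCTATGCTCCATTACG
TAAATAAGCAGAAATTTCCCAACAAGTTCAAT
>simg0002|exon|1
ATCCCACTTAGTTAGTTAGGATAAAGGGTACTATGGAATCATTTCGTTTTCATAGCAACGTAGGCGATTACTATTAGAAA
GCATATGGAAGA
>simg0003|exon|1
TGCCTCCATAAACTATGATAAATTGAACATCCGCTCTCATTAGTCTGTGCTCATCGATGCGCAGACATTATGTTGCGCTA
-TATCGTAAAATAATACGATTATTAACAGTACGAGGGGGGTTCCATGACAATAGAAAAAAAGAAGAGAACATATGCCTTG
AAGAGG
>simg0003|exon|2
CGAGGAAGTGGAAGAAGTAATATATCATACAAGGAGAAAGAACGTACTTCAATACACTTCCAACAATAATGTACGATACA
AATTACATGTTTCCTGTCTGTGTTCTATCGCAAAAGTTGCTATTGTATCAC
>simg0003|intron|1
CATTCAGGAGCTTCGCATTGATGTAAAGTTAACTTTAGAAAGGTAAGAAACTTAAAGTAAATGCAACAATGTAACATACA
AGACCTCTCTACTGGAATTAGAAGTGAGACTATATGAGGGATTATACTATTTACAAAGATTTCTGTTAAATTCGCAAGTC
GTACTTTATCCGGATATCATGTTTTTGTTAAATAAAAGTAGTCAGTAATAAGCAACAGATTACCCACAGTGGTACTTTTC
CAAA
>simg0004|exon|1
TTAGTTGATTTTCTTCGAGTATCCATGAGAAATCACTTTTTAGATGTCAACTAGGGAGACGACTCGTGTACTTGTACGCA
CAGTCAAGAAAGATTGTAGATAAGAAGAGCTAGG
>simg0004|exon|2
ATGCTAAGAAATATACCGCAGGGGTTAATGTGGGACGGTAAAGAGATTTGATTTACAGGAGTGCATCTGGTAGGAAATAG
AAAGAATATATATAGTATGATAGTTAAATAGT
>simg0004|intron|1
TTTCATTGGTATAAGGATTGTAACCGGATGTGCTCTCGACTTCTCAGATTTTATCATCAACGGACGCTGAAATACCTGGG
ATTAACTAATAGATTCGATCCACCTATAGGGTCCGAAGATCATAATGCTATTCAGAACGAAGTCATTAAACTAAACCAGA
TTAGACCTAAATTGCAAGTGAACGTATATGGATGGTATATCGATTATGTTCAGAATTTTAAGGTCAGCAAAACTTGATAA
TTATTGTCCTACCGACTTTGCTATTACTTAAATAAAACTGCTATTAAAAATACGCCAATATAGCCAGATCCTAATAATGG
AGTCAGTACATCTCTATAAGTAAGAGAATAATTC--ATCGCGCATAATCTCAGCAAGGAGACTTTTGTATAATCGCTCTC
CGTACTCTCGATTTACTAAGCCGTTATGCAGGTATTAGGCTCATGAAACATAATCTAAATTACCTTCTTCAGAGGTCGAG
TCTTAATAAACCCAAACAATTTTTTATAATCTATAATGCCGAACGCAAGGGCATGTGGTCTACTAAGGAATTATCT
>simg0005|exon|1
TTTTCAACTATGATATAGTTAACCGTTAACACTATGAATAGTCAGCTACTATCTGTACTAGCTTCGATTGAGCGGAAAAA
AGATAACTTAGCGACAATGTGTAAGGGGGTAGGGTTATCCAGATCATGTTGAAGAACGTCGT
>simg0005|exon|2
TAAGAAGCATCGTCCTA--CGTATATATATTAACAAAAGAAGCGTGTTGGAGAAGTTCTGAGGATTAATTTTAGGTCTTT
GCTTAACATGTCTTGGGGATAAAAGATCATCGCGAGAGAGATGTGCACATGCTCACCAAATTAGTGTGTCATAGTCCC
>simg0005|intron|1
ATTATCTGCGTTTCGGATCATTATCAGATAACCAAAACTTCAACAACCAAGGTATAAAATAGAAACGTGGCCTCAACAAG
TATCAATGTGGATGGTAATCGATTCGACTTGCGCTTATTTATAAGCTTGTTTATAAAAATTGGTCCCATATGCCGTTCCC
TGTTTTTTTTTTTATTTGTATATGCACTCAATTTTCGGATTTGAGACTCTACATCTTCGATTAAATACGTTCCAACAGCA
GGCGTAGCGTGTATCTATAGCAATGTAACTATTGTTATTACTATGAATGACCCAATCTGTGCTTAATTATGGGACATATT
AACTGATATGCATAATGGGTATTTATATAATAA
>simg0006|exon|1
GTCATCATAATAGTCGAAAGGCGGGATGCACTCCGTAGGGAGATAGCAAAGTACAAAGAGTAGTTGATTATAAGAGAGAG
TAGG
>simg0006|exon|2
AGAGGAAGAAGTATGGAGGGAAAAAAGAAAGAGACGATTAGTTTGTGG-AGAAAAATTCTGAGGAGAAATATCCGAACGC
TAATAAGGTTTATTATTTAAAATCGAAACGGTTCAATTCTTTCGTTTAATA
>simg0006|intron|1
GATGGTCCCAAGACGAAGCTTTGTCACTTTTCAAACTGGCCATAACAGGTAGTGTCATATAATGTTAACTAACAACGTCT
GACTTCCACTCCGCAAATCAAGTTCAAACAACGGGAAGTATCTGCACGCCGGAGGTTCAGTATAAATCTAAGTCGATGAC
TCATGATCGCAGAATCGCAGAGCATTTCATTAATACCTC--ACTAGGGTGGACTTGATCCTTCGAAACTCGTGTCTTTCT
AAAAACAATGATCATAATTGTGCGACTATTATGGGTGAGTAGTTAACATGGATGGAACACGTTTTACCTAGTAAAAAGTC
CCTTAAGTCAATGCTTTCGTGAATTCGATAATATACGCCCTGTTTTAAGTGCACAGTTAATCGCAATCATATATAAACTA
GGAAAAGG
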