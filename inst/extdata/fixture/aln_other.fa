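>simg0001|exon|1
AGTCGAATAAAATGATGTGAAAATGTTAATTTTAGGGAATGGAGATTGATCTAAGGATTCACAAAATTACATTTTAAAGG
AA
>simg0001|exon|2
AAAGGAAGAAGGGAGGAGGAAAGGGGAGGTTTTAACTCTTCCGACCTCAAGAAATTGCAAACAGGGTGATATACTCGAAT
GCAT
>simg0001|intron|1
AT----CAGTCAAGGTCCCGATGTGTATATGTATTTCCATGCCTAAACGTCTTTGCCTACAAGGTCCACTTGACCTTTTG
TGTTAGTTAATTTGGAGAAAATCATGTGTTTGTATTCGTTTAAAAATAATTGACCCCATCATGTACTGAAGAACGGGGTA
GCATAGAAAAAAGTCTATGTAGTGCGAATTATTGCTGACATGGAAAATAGGATAGAATAAGAATGTTATGCTCCATTACG
TAAATAAGCAGAGATTTCCCTACAAGTTCAAT
>simg0002|exon|1
ATCCCTCTTAGTTGGTTAGGATAAAGGGTACTAGGGAATCATTTCGTGTTCATAGCAACGTAGGCGATTACTCTTAGAAA
GCATATGGAAGA
>simg0003|exon|1
TACCTCCTTAAACTACAATAAATTGAACATCCGCTCTCATTGGTCTGTGCTCATCGATGCGTAGACATTATGTTGCCCTA
TTATCGTAAAATAATACAATTATTGACAGTACGAGGGGGGGTCCATGACAACAGAAAAAGAGAAGAGAATATATGCCTTG
GAGAGG
>simg0003|exon|2
CGAGGAAGTGGGAGAAGTAATATATCATACAAGGAGAAAGAATGTACTTCTATACACTTCCAACAATAATGTACGATACA
AATTACATGTTTCCTGTCTGTGTTTTATCGCAAAAGCCGCCAGTGTATCCC
>simg0003|intron|1
CATTCAGGAGCATCGCATTAGTGTAAAGTTAACTTTAGAAACGTTAGAAACTTAAAGAAAATGCAACAATGTAACATACA
AGACCCCACTGCTTGAATTAGAAGT-----TATTTGAGGGATTATACTAGTTACAAAGATTTCTGTTAAATTCGCAAGTG
GTACATTTGCCGGATATCATGTTTTTGTTAAATAAAAGTAGTCAGTGATAAGCAACAGATCACCCACAGTGGTACTTTTC
CAAT
>simg0004|exon|1
TTAGTTGATTTTCTTCGAGTATCCATGAGAAACCACCTTTTAGATGTCAACTAGGGAGACGACTTATGTACTTACACGCA
CAGTCAAGAAAGATTGTAGATAAGAGGATCTAGG
>simg0004|exon|2
ATGCTAAGAGACATACCGAAGGGGTTAATATGGGACGGTAAAGAGCTATGATTTACAGGAGTGCATCTGATAGTATATTG
AAAGAATATGTATAGTATGATAGTTCAATAGT
>simg0004|intron|1
TTTCAGTGGTATAAGGATTGTAACCGGATGTGCTCTCGACTTTTCAGATTTTATCATCAAAGCACGCTGAGATACCTGGG
GTTCACTAAAAGATTCGACCCACCTATAGGGTCCGAAGATCTTACTGCTATTCTGAACGAAGTCATTAGGCTAAACCAGA
TTAGACCTAAAATGCAGGTGAACGTATATGGATGGTATATCGATTATGTTCAGAATTTTAAAGTCATCAAAACTTGATGA
TAATAGTCCTACCGACTTTGCTATTACTTAAATAAAACGGCTATTAAAAAAACGCCAATATAGCCAGATACTAATAATGG
TGTCTGTACATCTCTATAAGTAAGTGCATAATTCTAATCGCGCATAATCTTAGCAAGAAGACTTTTGTATAATCGCTCGC
CGTACTCTCGATATACTAAGCCGTTATGCAGGTATTAGGCTCATTAAACTTAATCTAAATTACCTTCTTCAGAGGATGAG
TCTTAACAACCCCAAACAATTTTTTATAATCTATAATGCCGAATGTAAGGGCATCTGGTCTAATAAGGAATTATCT
>simg0005|exon|1
TTTTCCACTGTCAGATAGTTAACCGTTAACACTATGAATAGTCAGCTACTACCTGTACTAGCTTCGATTGAGCGGGAAAA
AGATAATCTTGCGAAAATGTGTAAGGGGGTAGGGTTATCCCGAGCAAGTTGAAGAACGTCGT
>simg0005|exon|2
TAAGAAGAATCGTCCTAGACGTATATATATTAACAAAAGAAGCGTGTTGGAGAAGTTCTGAGGATTAATTTTAGGTCTTT
GCTTAACATGTCCTGGGGATAAAAG-TCATCGCGAGAGATATGTGCACATGCTTACCAAATTAATGTGTCATAGTCCC
>simg0005|intron|1
ATTATCTTCGTTACGGATCAATATAAGATAACCGAAACTTCAACAACCAAGGTATAAAAAAGAAACGTGGCCACAACAAG
TATCAATGTGGATGGTAATCGATTCGACTTCCACTTATTTATAAGCTTGATTATAAAAATTGGTCCCATATGCCATTCCC
TGTTTTTTTTTTTATTTGTATATGCAATCAATTTTCGGATTTGAGACTCCACATCTTCGATTAAATAGGTTCCAACAGCA
GACATAGCGTGTTTCTATAGCAAAGTAACTACTGTTATTACCATGAATGACCTAATCTGTGCTTAATTATGAAACATACT
AACTGATATGCATAATGGGTATTTAGAGAATAA
>simg0006|exon|1
--------------------------------------------------------------------------------
----
>simg0006|exon|2
-----------------------------------------TTTGTGGGAGAAAAATTCTGAGGAGAGATATCCGAACGC
TAATAAGTATTATTATTTAGAATCGAAACGGTTCAATTCTTTCGTTTAATG
>simg0006|intron|1
GACGGTCCCAAGACGAAGCTTTGTAACTTTTCAAACTGGCCATAACAGGTAATGTCATATAAAGTTAACTAACAACGTCT
GACTTCCACTCCGCTAATCAAGTTCAAACAACGGGAAGTATCTGTACGCCGGAGGTTCAGTATGAATCTAAGACGATGAC
TCATGATCGCAGAACCGCAGAGCATTTCATTAATACCTCATACTAGGATGGACTTAATCCTTCGAAACTCGTGGCTTTCT
AAAAACAATGATCATAATTGTGCGACTATTATGGTTGAGTAGTTAACATGGATGCAACACGTTTTACCTAGTAAAAAGTC
CTTTAAGTCAATGTTTTCGTGAGTTTGAGAATATACGCCCTATTTTAACTGCACAATTTATCTCAATCATATATAAACTA
GGGAAAGG
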