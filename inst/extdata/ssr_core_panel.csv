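name,primer_f,primer_r,chromosome,size_min,size_max
SSR101,TGGAGTGTTTGTTGTAAGCTCAA,TTCGGGATGAGAGTTCCAAG,5,188,227
SSR125,TGCTCTTTGACACGTGCTATC,AGAGGAGAGAAGGGGAGAGG,1,110,139
SSR136,TGATCACTGGGGTCCATTTA,CTGCGTCGAAGTTAGAGACG,2,153,203
SSR138,TGCGTGCGGATTATCATCTA,GGACGTAAACTTAGCACGATTC,2,160,174
SSR192,TAATCGCGATCTGGATTCAC,ATCAGAACAGCGACGAGGTC,5,114,162
SSR198,GGTCAGGTGCTACTCAGACTCC,TTGAAGAGGATCCACCAAAAG,3,276,314
SSR206,TGTCAGTGTGTCCACTTCGC,AAGAGAAACCCAATAAAGTAGAACC,8,124,207
SSR207,TCAGCCTACCAACGAGTCATAA,AAGGTCTCATACGATGGGAGTG,6,144,213
SSR22,ATGCACAGAGGAAGAAACCG,GGGGATGAAGAAGAAGCAGA,1,155,191
SSR221,GTTCTCAAAGGGAAACCGAAAAACA,GAGTTGGCCAGAGATTTACATGCGT,4,99,178
SSR222,CAAGAGCAAGTTTGAAACAAACGAT,CATCAGTTCTTGATATGCTAGGTGA,6,175,280
SSR227,TTCCACCTCTCTGCTCCAAC,ATGCGTGAGCGAGGATAACT,2,271,355
SSR228,GGAGTCCACTTCATGGAGGA,CTCTTGCTCGTAGGTTTCCG,8,233,274
SSR229,TCAGTCACAAAAAGTCAACTCAAA,ACGGAGTAGGAGTTGGGAGG,9,114,148
SSR238,TTTGACATCGTGCAATGCTA,TTGGGCTGGTCCTGAAGATA,3,278,325
SSR247,GGTCCATTCCTTTTTGCATCTG,CATGGCAAGGGGTAACAAACAT,7,128,154
SSR256,GGAGCCAGGAGAGAAGAAGG,CCCAAAACTTCCAAGAAAAGC,3,168,206
SSR266,TCGGATTTGCATGTTCCTGA,CCGATACACAACCAGCCAACT,7,187,305
SSR283,CCAACACCAAATCGCATAATC,GGAGCTCCCACCTACAGTTTC,10,163,182
SSR45,GATTTGGGCCATTTGGATTA,TTGAGCATTGTTCCCAGACA,4,206,230
SSR56,GTTAAGTTCGAACGCGAAGG,GATCGGGGAAAATTAGGGAA,9,241,272
SSR66,ATTCAAAGACAAAGGAATGCCTGAG,GTTTCTTTGATCCTGTCGAATGGCATTAATAAA,6,123,144
SSR90,TGCCTTTGTGTTCAGCTCAC,CCCAAACGCTTTTGACACAT,10,202,211
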