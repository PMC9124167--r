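>synthetic_example_g00001 synthetic CDS
ATAGGACCCGACTATTACAAGGATACCTCCTACCCCCTTCTCGCAATGAGCGTCCACGAGTCCAGTCCACGGCGCTTCGGCATGGAGTCTATTTGGCCCCACGGGGACTTTCGCGCGTACGCGGTCTAA
>synthetic_example_g00002 synthetic CDS
ACTTTTGACCGGGGGGTGGTGACAAAGCTTAATTATCCCCAGTACACCCTCGACTATTACGGGACGGAGGACGCTGACAACCATAAGCCCTGA
>synthetic_example_g00003 synthetic CDS
TTGGGAGACTTTATGTTCGGGACCCGTGTGCCCACAGAATTACCACAGGATCAATTCGGTCCGCTTCTGCGGGTACGGGTGAGAGCCTTGGATACATAA
>synthetic_example_g00004 synthetic CDS
TTGAGCAAGATTGTCCTATTTCTATTAGGGTATGCCATTTACAATTGTGTTCTTCTAATTGCCAGGTATGCCTTCGAGCATAAGACTTAG
>synthetic_example_g00005 synthetic CDS
GTGGCGGAGGAACTGAAGCACAGAGAATTTGACCAAGGTTATCTCGTCCAAGTGCTCGTCCTGGTCCGTCTCATAGAGCTGATATGCGCCCCAGTGCTAAGCGAAGGAGAGCGGAAAGGTGACTGA
>synthetic_example_g00006 synthetic CDS
GCGATCGTTCAACATATCCTGGGCAACATTGCTGGCGGAGCATTGGACCCTGAGAACGCGGATATAATTAGGGCTGCGCGCCTCGACCAGCATATTAGTGTTGACATGTAG
>synthetic_example_g00007 synthetic CDS
GTCACGCTAGCTGATGTTGGTGTAGGCAAATATGCTAATTATGAGCGCATCGAGCTGGTGCTAGCTAGATACAGTGCCTCAGGGGCAGTGTCATACTACGTCGTCTATAAATATATCCACCCGAGAGGTAACGGACGTACATGA
>synthetic_example_g00008 synthetic CDS
GAAGAAAATAGTCCCTCCCGTTCAGAGGATCATGCCCTGACTCTCCCAAACGTTCAGTATGACTGCGGGGCTAGTATACACAGTACTGTTGTCGTTATATAG
>synthetic_example_g00009 synthetic CDS
GGATTTATTAGCCAACGGAAAATTAAAAACAATGATGATCTCACTTCTAGACAAGTCGAGGTTTTCATCAACGGACATGAAGCAATGATGTCGTTGCAGGTTGTGTAA
>synthetic_example_g00010 synthetic CDS
AGGCTCCCGATGTGTGCAGTCAAGTATGGAGTAGCCGCTCCGATGGACTTTGTTGATGAAGGTGAATTGAGCGCAGTAGATGGGGTCTTCTTGATAACATATCTAAGGACCCCATTGCGCTAA
>synthetic_example_g00011 synthetic CDS
CTGGCTTTATACTATGTTAACCTCGAGTGTACCCAGCACGAAGAAGTCCAGGAGGATTGGGCACCGTCGTATAGCTCCTTCGTCTATATTCAGCTTACCACCGGAAACAACGTCTGA
>synthetic_example_g00012 synthetic CDS
GGCGTTGACTACGGACATATACTATTCGTCAGTGAACAAGACGTGATTTTAATGCGGCCATATACAGATAAGAAAGAGTACGGAGATTGCGATACGGCATGCCAGAATGTGCACGGAATGAAGGTAACTAAGACTATCGCATGA
>synthetic_example_g00013 synthetic CDS
AGCCTCACTGCCTTAACCTGGATCCACGATGGGTCAAGGGACGTCCCGATGATGTACGAATCTACTAAGCCAATGCGGGGCGAGATGGGACCCGAAGCGTCCAAGCGCCGACCACATACGAGGGTTCGTAAAGTTATCGGCCCACATGCTGTCGTGGATGCAGGTTTAAATAACGAGTAG
>synthetic_example_g00014 synthetic CDS
GGGGTGGCGCTCTTTGATAATGTCGGAAGAATCTACAAAGTGCCTTACGGAATCAGCGATACTTCCGACTCTCCGGCCCAGGCTGGGGCGTTAGTGGTTTTGAACCTGCTTACAGAGTAA
>synthetic_example_g00015 synthetic CDS
ATAGCTGGAGACGTCCATCGTGTGGGGGTACACGGAAGACTAGGCATGTCTCCTTCCTTAATCTATAATTACACCAATTTAGAACTGTTTAACAACGAGGTAAGTACCGGGGAGGGTGCCATTATCGTCCCAGACCGCACAAAGTTTTGGAAGATTGATTAG
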