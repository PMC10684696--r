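>NAT2_coding_reference_synthetic 873 bp synthetic stand-in for the NAT2*4 coding exon
ATGATACATACGCGTCTAAAAGGAATCAGGGGCCCTAATAAAGCCTCCGACTCAACCACC
AGCGTCTACCACAAGACTATGCGTTTCGTCCAAAGTGTGGGCAATCCTGACTGTTGTATT
AGAAGAAGGGTTCGACTCTGCGATTGGGGGTTCCACCACGTTCGCGGGGCATCTCACCTA
AGGGCAGGGCGAATAGTCTGCGTGAAGCTATTGTCCCCGCTCTCGGTGTACGGCCCTAGC
CATTGCCCGGCGTTGACTCTCTGCATGCCCGACCCGTCTTACCGGTGCACAACTACGCAT
CTGGGACTTGCCAGTCAGACGAGGGCCGCTCACACATTGATTGTCCACCTGCTCTGGGGA
GACGCCTCGAAGCTACCCACCGGCTTGACAGCGGCACCACCCCGCCAAGAAACTCGAACT
GATGGGTTGCCTAGCCGGCGCTATGAACTTACATCCATCATTGCCCTTTCGAGCACTCGG
CTGCAGGAATGCAAGCGAACGATTGCGGTTAGTCCTCATTCTGACTTTGGACCTTTTTGC
CCCACCAAGCAAAGGGAATCTTCAGAGGCCCATCGGTCTTTTCACGACCGAGGCAATGAA
GAAATGCTGCACTTGACTAAGTTAGGTACACACATACCCGCTTTCGAGGATACAAGGGCT
GGGGCGTGCCAGACCCGTACTGCTGCAACCGGCGCTGGTAATGAACTCGTTGCTACAAGA
TTGCCGCCAGGGTCGTGTACGCATAGGACGAGGTCCCCTAGCGTTTCGGAATACGTCAAA
GCTTGGCGACGTATAAGATTTAAATTATCAAAGTATAAGGGCGGCAGCCCCTTAACGTCG
TACAATCGTCACATCGGACGGAGTCGCAGATAA
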