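>allele4
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTCCTCCTTAATATTGAGAACCCGG
CTGAGGATTTGAGGGATCTTACCGGCGTTGGCTCGATGGACGGGTGGCCGTGTTCGGTGCTCCGCCACTG
TGACACAAGTCAGGGATTGGGGTCTTGTTCTGTCCCTAACAAAATCCAATACCTGCCACGCTACTATGGG
GGCTCCGGGGAACAAGTCCACACGCTAAACGAGCGTTACGCTACACTACCTCATCCCTATCGTTATCTGC
TCCTAAATAAGGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele6
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGTATTTGAGGGCTCTTACCAGCGTTGGCTGGATGGACGGCTGGCCGTGTCCGGGGCTCCGCTCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCCCTAAAAATATCGAATACCTGCCACGGCACGATGGG
GGCTCGTGGCAACCAGTGCGCACGTTTAACGAACGTTATCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAATAGAGAGGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele7
AGAATTTCGCATAGGTGGAGTCTTGTGGTCTAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGGATTTGAGGGCTCTTACCAGCGTTGGCTCGATGGACGGCTGGCCGTGTTCGGGGCTCCGCCCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCCCTAACAATATCGAATACCTGCCACGGCACGATGGG
GGCTCGGGGCAACCAGTGCGCACGTTTAACGAACGTTACCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAATAGAGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>WO2-contig
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTTTTCCTTAATATTGAGAACCCGG
CTGAGGATTTGAGGGATCTTACCGACGTTGGCTCGATGGACGGGTGGCCGTGTTCGGTGCTCCGCCACTG
TGACACAAGTCAGGGAATGGGGTCTTGTTATGTACTTAACAAAATCCAATACCTGCCACGCTACTATGGG
GGCTCCGGGGAACGAGTCCACACGCTAAACGAGCGTTACGCTACACTACCTCATCCCTATCGTTATCTGC
TCCTAAATAAGAAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>WO3-contig1
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGTACTTGAGGGCTCTTACCAGCGTTGGCTGGATGGACGGCTGGCCGTGTCCGGGGCTCCCCTCCTG
TCCCACAAGTCCGGGATTTGAGTTTTGTTCTGTCCCTAAAAATATCGAATCCCTGCCACGGCACGATGGG
GGCTCGTGGCAACCGGTGCGCACGTTTAACGAACGTTATCCTATACTACCAGTTCCCTTTCGCAAACGGC
TTTTGAATAGAGAGGCGGCGCTTGGCCTCGCCAACCGTTGNNNNNNNNNNNN
>WO3-contig2
AGAATTTCGCATAGGTGGAGTCTTGTGGTCTAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGGATTTGAGGGCTCTTACCAGCGTTGGCTCGATGGACGGCTGGCCGTGTTCGGGGCTCCGCCCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCCCTAACAATATCGAATACCTGCCACGGCACGATGGG
GGCTCGGGGCAACCAGTGCGCACGTTTAACGAACGTTACCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAATAGAGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
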