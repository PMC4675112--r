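>allele1 individual:604FB status:unresolved
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGAAGAGTTCCTCCTTGATATTGAGATCCCGG
CTGTGGATTTGAGGCCTCTTACCAGCGTTGACTCGATGGACGGGTGGCCGTGTTCGGGGCTCCGCCACTG
TCACATAAGTCCGGGATTGGGGTCTTGTTTAGTGCCGAACAAAATCCAATGCCTGTCACGGTACGATTGG
GTCGCGGGGCGACAAGTGCACACGTTTAACGAGCGTTACCCTACACAACCTGATCTATATCATAATCGGC
TCCTAAATAAAGAAGCGCCTCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele2 individual:641U status:uninfected
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTCCTCCTGGATATTGAGATCCCGG
CTGTGGATTGGAGGGCTCGTACCATCGTTGGCTCGATGGACGTGTGGACTGGTTCGGGGCTGCGCCACTG
TCATACAAGGCCTGTATTGGGGTATTGTTCTGTCCCTAACAAAATTCAATACCTGCCACGGTACGATGGG
GGTTCGGGGCAACAAGTGCACACCTTTAAGGAGCGTTACCCTACACTACATGGTCCCTATCGTAATCGGC
TCCTAAATAAAGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele3 individual:603B status:infected-B
NNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNAGTGTCGGGCGAGTTCCTCCTTAAGATTGAGAACCCGG
CTGAGGATTTGAGGGATCTTACCGGCGTTGGCTCGATGGACGGGTGGCCGTGTTCGGTGCTCCGCCACGG
TGACACAAGTCAGGGATTGGGGTCTTGTTCTGTCCCTAACAAAATCCAATACCTGCCACGCTACTATGGT
GGCTCCGGGGAACAAGTCCACACGCTAAACGAGCGTTACGCTACACTAACTCATCCCTTTCGTTATCTGC
TCCTAAATAAGGCAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele4 individual:169U status:uninfected
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTCCTCCTTAATATTGAGAACCCGG
CTGAGGATTTGAGGGATCTTACCGGCGTTGGCTCGATGGACGGGTGGCCGTGTTCGGTGCTCCGCCACTG
TGACACAAGTCAGGGATTGGGGTCTTGTTCTGTCCCTAACAAAATCCAATACCTGCCACGCTACTATGGG
GGCTCCGGGGAACAAGTCCACACGCTAAACGAGCGTTACGCTACACTACCTCATCCCTATCGTTATCTGC
TCCTAAATAAGGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele5 individual:167U status:uninfected
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTCCTCCTGGATATTGAGATCCCGG
CTGTGGATTGGAGGGCTCGTACCATCGTTGGCTCGATGGACGTGTGGACTGGTTCGGGGCTGCGCCACTG
TCATCCAAGGCCTGTATTGGGGTATTGTTCTGTCCCTAACAAATTTCAATATCTGCCACGGTACGATGGG
GGTTGGGGGCAACAAGTGCACACCTTTAAGGAGCGTTACCCTACACTACATGGTCCCTATCGTAATCGTC
TCCTAAATAAAGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele6 individual:180F status:infected-F
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGTATTTGAGGGCTCTTACCAGCGTTGGCTGGATGGACGGCTGGCCGTGTCCGGGGCTCCGCTCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCCCTAAAAATATCGAATACCTGCCACGGCACGATGGG
GGCTCGTGGCAACCAGTGCGCACGTTTAACGAACGTTATCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAATAGAGAGGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele7 individual:603B status:infected-B
AGAATTTCGCATAGGTGGAGTCTTGTGGTCTAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGGATTTGAGGGCTCTTACCAGCGTTGGCTCGATGGACGGCTGGCCGTGTTCGGGGCTCCGCCCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCCCTAACAATATCGAATACCTGCCACGGCACGATGGG
GGCTCGGGGCAACCAGTGCGCACGTTTAACGAACGTTACCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAATAGAGAAGCGGCGCTTGGCCTCGCCAACCGTTGGCCTGGGCACGC
>allele8 individual:186U status:uninfected
AGAATTTCGCATAGGTGGAGTCTTGTGGTCCAAGTGTCGGACGAGTTGCTCCTTGATAATGAGATCCCGG
CTGTGGATTTGAGGGCTCTTACCAGCGTAGGCTCGATGGACGGCTGGCCGTGTTCGGGGCTCCGCCCCTG
TCCCACAAGTCCGGGATTTGAGTCTTGTTCTGTCGCTAACAATATCGTATACCTGCCTCGGCACGATGGG
GGCTCGGGGCAACCAGTGCGCACGTTTAACGAACTTTACCCTACACTACCAGATCCCTATCGCAAACGGC
TTTTGAAAAGAGAAGCGGCGNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNN
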