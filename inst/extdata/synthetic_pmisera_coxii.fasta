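>P. misera synthetic COXII-like template|COXII|synthetic
GGATATAACTCTAGACGCCATAACCGATAATCCGTCTGGTTACTGATGGCCTCTTGCGAACTCTCGTAAT
CGTACCCACATTCTGAGACACTCGGACGTGGCTCGATACACTAAAGTGGAATAGGAAGTTCCACCCGATG
TGTCTCACCCGGAGTGTATGGAAGGTTAGGAATCTGGGATACTCTACCTGTGGTCTGCTTTGCGGAATAG
AAGTAATCCCCTGAATTGTCTTAGAGCCCTTGATACTTCCATCCGGTATTTTTCACTTTAGATACTCGAT
GCATAGCACCGACACCCCGCTGGAACCCCTGGACGACTTATGCGGGATGGGTCTTGTAGCGCGTATAGCC
GACATTAAGCAACTTGCTAACAAGCGATTTGCGGAGCTAATCACAGTGACCCGGTCTCGTCCATGGGGGT
GTTGTAGACTGGTGAATGTCGCTTAACGCACTTCGCTAGATACGGTCCCAGCGCAAAATGCATGATTCAA
CTCCTTCGCTTAATGCTACGGGGCCCCGAAGTAATCTCATAGCATTAGATAGGGATGGTGTGCCAGGAGC
GTAGAGTAGTGTATACGCTTGAGCAGACACCTAACCGAGTTGAGGCGGTCCACACAGCTTCCTAACCACG
GTTACGAGTTGGAGTGTTATGCTATTAATTTGCGAACTCTGTCCCTTTTAGCACTTCACCG
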