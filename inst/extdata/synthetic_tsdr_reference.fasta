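>TSDR|strand=top
CCTTGTATCTCTCCACTTACCTTGTTAAAGCGACATGGATGGCCACACAGTACACCTTCACCCGAGGTGGTGATGTATAT
GCCCTATCGCTTTAATTCCACAAAGCCACAATAGGAACGAGGTGGGCCCATACCCAGCCCCACGAGGGGGTGACTCTTAT
GAGAACTGCAGAAGAGACGATGGAGGCATCCAGTTGTGAAACAAAAGGACGACTTGCAGCATGCTCAGAAGGCAGTCAAG
TCCGCACATGTGACTCAATACATTGATCCGCTTCTCCATTCCTTTCAGAAATTATCTTCTTACGCCTACTATTCTATCTC
AAGGGGGCCCCCGGTGGGGAACCCACTTGAACCAGGCCCCCGGCTCACACAATCTTGTTGCAGCACCGGTCCTTCTGCAG
CTTAAGGGTGCTGCCCGCACAGGCATATGCCATAGGACAATGGGCGGATCTTGAGTCCCCTGACCTGCTTAGATTT
>TSDR|strand=bottom
AAATCTAAGCAGGTCAGGGGACTCAAGATCCGCCCATTGTCCTATGGCATATGCCTGTGCGGGCAGCACCCTTAAGCTGC
AGAAGGACCGGTGCTGCAACAAGATTGTGTGAGCCGGGGGCCTGGTTCAAGTGGGTTCCCCACCGGGGGCCCCCTTGAGA
TAGAATAGTAGGCGTAAGAAGATAATTTCTGAAAGGAATGGAGAAGCGGATCAATGTATTGAGTCACATGTGCGGACTTG
ACTGCCTTCTGAGCATGCTGCAAGTCGTCCTTTTGTTTCACAACTGGATGCCTCCATCGTCTCTTCTGCAGTTCTCATAA
GAGTCACCCCCTCGTGGGGCTGGGTATGGGCCCACCTCGTTCCTATTGTGGCTTTGTGGAATTAAAGCGATAGGGCATAT
ACATCACCACCTCGGGTGAAGGTGTACTGTGTGGCCATCCATGTCGCTTTAACAAGGTAAGTGGAGAGATACAAGG
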