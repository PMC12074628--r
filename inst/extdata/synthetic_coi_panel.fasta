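>Rattus_norvegicus
GTCCCCCTCGGCGCTAAGGCGTTCGTTCCCAAAAGCCGCACCTATATACATCACTCACTGTCCCCTCGAAAGAATGCCTCCAATCTACCTTCTTTCCCTCGTGTATCAGCGTTAGACGGGAGTCAGATGTATTAGTTAGGCCCCTCGATAGATGCGCTTGGCAACACGTCGTGCTTGAGCGTCCTTGTCATTTACGTGTATCGGTAGTGCACCGACTACCAAGTGTGTATCTTTGTCGGCTAAATAAGGGCCGCGTACCGGTTACCCCTGAGGTTCAGGAGTTCTTCACGGTGACAGGCCCTCTTGAAGATGAATTACGTCCATGCGGCATTCAACGGTGGAAACTTTCAAGGATTCTTTGGAGTATAACAGGGGAGTCTGGGATAACCGCGTTCATCTTACAAGAGATCGTTTCTGGGG
>Rattus_rattus
GCCGAGCACAGGTGAGTGCGACATGTAAACGGCTCTACGTGGCGTTCGCAAGCCGATCTGTGTATACAATAGCACCCGCGGATGTGATTTATACTCAAGACAAGCACGACAACCAAAGCCGCCAACAGAGTGTGTTCTGTTTCCTGTCTAGTCTCATCTTAAAATATCTCTACATGACAGGACGGCCAATTTCTGACCCTGTGACGACGACGTCATTTGTGTTTATTGCAATATCGCTGGAGGGTTCGTGGGTTCGGTGGCGGGTTCAAGCGGACCAACTAGACCAGGCGGTCGGTCTGCCTTAGGGAGCTGACAGGGTTGTCGCCACCGTAGGCGAGCCGGAATGATCATTTGAGAGTTCTAAATGGTCAGGAGCCCATCAATACTTTTATGGTGTTCGTGGTACCACTAGGAGAAAGC
>Mus_musculus
CTCAAGGTAGGGCCCCCCAAGAGTGTTGAAAGTATCGTCAGTTGTTCGCGAAATCCTTGTTGCCTACTGTGGTGGTACGGAGTTGATCAATCTTATTACTTTGGTGAATGTCCCTTTAGGTGCTCTGTGCCCCTCAATTAGGTAGAGGCGAGGCCAGAAAACGTAACAGGAAGTTACTGTGAAAATCCTTCTCACAACGAGTACCGGTGTGCTGATCCATTGGAATCGCGTGGCCTATCGGGAGATGAAGTAGGATCCCGCCAGGATTGTATTGAGTTCTACTTATCCTGTGAGCAACTACGCCGTTCGGCCTGGCGGTGAGGTCCAACAGCAGACCTCCCGCTGTTCCAAGCGCCGCCACAACTCCAATGAAGTGGGAACTCCTGGCACGACGACCCCGTGAACTTAACAAGTTAGAAC
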