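>L2like_synthetic
GTAGACTCACCTTGTTGCGTAGGGCCCTCCTTAAAGCAACACGAGAGTTAACATTCGACC
ATTCCCTCGATGGGGTAACTTGTTTGTCAGTTCTTGTTGCAAATGTCTGTATGAGGTCAT
TGCGTCTGAGCGCTCACTTCGTTACAGGTTAATCCTTATTAATCTAAGTATGCAAGGGTG
TAGCCATAATACTTTCTAAGCACGGGCTTATTTCTCTTCTATTCAAGGAAATATAGGTCA
CTAATAGATTATCCTTAATCCAGTTAGAGGACTTGGAGTATGACTTCCCGTCGAAGCTTA
>MIRlike_synthetic
CCGTTAACTAGATCGCCCCGCGCAGGTGCATGCTAACTCGGCCTTCCTATAGGCGTGCGT
TCCTGTTTACTAGCGTGACGCTATGGCGAGACGTCAGTGCGTATATAAGGCTACCACACA
CGTATTTTGCGCAATCTTTGTTATGTCATATAACCTCGAACCTCTCATTCGAACATCGTC
ACCCACGCCTGACAGGAGTCAACGAGTGACTTATACACCCTAGCGAGTTGGCGCATGCAA
GCTGCCTAAGCACCTGGGAC
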