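>p4 50-nt predator, low overlap with res (omega = 4)
GGTGCGCGTGGCAAACGGGGCGTTGTGGGGCGTGCAGCGCTGACGGTCAA
>p10 50-nt predator, high overlap with res (omega = 10)
GCGGTGCACGCAACGCCGGATGCGAGGGTGCTTGTTGCGAGGGCTGCTGG
>res 20-nt resource strand
CGGTATTGGACCCTCGCATG
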