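>allele1
CGGTGCGGCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAG
>allele2
CGGTGCGGCTTGTTCGTGCTGTTCGGCTCGACGCCGCTCTGTTAGCTAGAATAACTAGAG
>allele3
CGGTGCGCCTTCTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAG
>allele4
CGGTGCGGCTTCTTCGTGCTCTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAG
>allele5
CGGTGCGGCTTGTTCGTGCTCTTCGGCTCGACGCCGCTCTGTTAGCTAGAATAACTAGAG
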