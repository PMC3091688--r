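>alpha_exon1
ATGTTTCCATGGTTGGTAGTCAACGAGTGCTCTTCCTTTACTAATAAGCCTGAATGGCAGTACGCGTTTCATGGCGGGAT
CAACCGCGTGAGC
>alpha_exon2
TTCTTCATCCCGTGCAAATACGAAATGTGGACATTTGAGTGCGCACATTATTGGTGGACGAACATAGTCCACGAGCGATA
CGAATGCCGTTCCCCATGCGGTCAATGTGCATGGTGGTACGGATGGGGGCTCGCGCGTTGGCAGTTTATGAACTACACCT
GGTTTGTCGACATAGTTATGATGAACAAGAGGGCACTGATGTCACGCAATGGC
>alpha_exon3
ATATGTTTAAATGCACAACCCATGATGATGCCAGACCTCTGGTGGCAAAAACATCATACCGTTCAGCAAGACATGACAGT
TCACAGCCGCATAGAGGCCCACAAAAATAAACAAAAAGAGTTTTAA
>beta_bohr_exon1
ATGCCCCTGGGTGAGCTTCATAGAAAGGCTGGTGTGTGGCCACCCTGTAAGTGCCGTCTGGCCGTGCAGGGTGACAAACC
ATGGATCCACCTC
>beta_bohr_exon2
ACAGACCATTGGCAGGGTCCTATGCACTGTGACATGGGTAATGTTACGAAATGGCCAGCGTTATGGATGAAATATGGCTT
CCGGGGGTTCAAAGTCTGCCAATACTGTTGTACGTATTGTGTTAAGGTAATTCACATCAAATGCTACACTAACTTCCGGA
TCTGTAACGAGTCATGGGACCAAGGACTAACGAATGATAACATGCGGGTCAACTGCTGCTGG
>beta_bohr_exon3
GACTGGCAGAGATGTATGTCAATGCACATGATGCACAACCTCATGATCGCAGGGGTCGTTTCAATGACCTGGTCTTTTAA
CCTTTACAGTTCATGTGGTCTCGGCCTGATGGCCGCAGAGAAGAAACATTAA
>beta_nonbohr_exon1
ATGCCCCTGGGTGAGCTTCATAGAAAGGCTGGTGTGTGGCCACCCTGTAAGTGCCGTCTGGCCGTGCAGGGTGACAAACC
ATGGATCCACCTC
>beta_nonbohr_exon2
ACAGACCATTGGCAGGGTTCGATGCACTGTGACATGGGTAATGTTACGTACTGGCCAGCGTTATGGATGAAATATGGCTT
CCGGGGGTTCAAAGTCTGCCAATACTGTTGTACGTATTGTGTTAAGGTAATTCACATCAAATGCTACACTAACTTCCGGA
TCTGTAACGAGTCATGGTGCCAAGCTCTAACGAATGATAACATGCGGAAAAACTGCTGCTGG
>beta_nonbohr_exon3
GACTGGCAGAGATGTATGTCAATGCACATTATGCACAACCTCATCGCAGGGGTCGTTTCAATGACCTGGTCTTTTAACCT
TTACAGTTCAACAGGTCTCGGCCTGATGGCCGCAGAGAAGAAATTCTAA
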