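>alpha_exon1
MFPWLVVNECSSFTNKPEWQYAFHGGINRVS
>alpha_exon2
FFIPCKYEMWTFECAHYWWTNIVHERYECRSPCGQCAWWYGWGLARWQFMNYTWFVDIVMMNKRALMSRNG
>alpha_exon3
ICLNAQPMMMPDLWWQKHHTVQQDMTVHSRIEAHKNKQKEF
>beta_bohr_exon1
MPLGELHRKAGVWPPCKCRLAVQGDKPWIHL
>beta_bohr_exon2
TDHWQGPMHCDMGNVTKWPALWMKYGFRGFKVCQYCCTYCVKVIHIKCYTNFRICNESWDQGLTNDNMRVNCCW
>beta_bohr_exon3
DWQRCMSMHMMHNLMIAGVVSMTWSFNLYSSCGLGLMAAEKKH
>beta_nonbohr_exon1
MPLGELHRKAGVWPPCKCRLAVQGDKPWIHL
>beta_nonbohr_exon2
TDHWQGSMHCDMGNVTYWPALWMKYGFRGFKVCQYCCTYCVKVIHIKCYTNFRICNESWCQALTNDNMRKNCCW
>beta_nonbohr_exon3
DWQRCMSMHIMHNLIAGVVSMTWSFNLYSSTGLGLMAAEKKF
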