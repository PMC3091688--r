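required_exon_count: 3
required_intron_count: 2
alpha_protein_length: 143
beta_protein_lengths:
- 147
- 148
nonbohr_protein_length: 147
nonbohr_cterm_residue: F
nonbohr_position: 93
nonbohr_position_residue: A
nonbohr_position_includes_met: yes
donor_dinucleotide: GT
acceptor_dinucleotide: AG
exon_size_slack: 2
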