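name	insert_seq	insert_position	offset	source_tag
identity		three_prime	0	guidecraft-identity
hairpin	GCACCGACTCGGTGC	five_prime	0	synthetic placeholder stem-loop; confirm sequence before wet-lab use
GOLD	GGCACCGAGTCGGTGCTTTT	three_prime	0	synthetic placeholder; confirm sequence before wet-lab use
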