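group	is_rt	msa_a	msa_b	msa_c
ExampleDuplorna	FALSE	ExampleDuplorna.A.fasta	ExampleDuplorna.B.fasta	ExampleDuplorna.C.fasta
ExamplePisu	FALSE	ExamplePisu.A.fasta	ExamplePisu.B.fasta	ExamplePisu.C.fasta
ExampleRT	TRUE	ExampleRT.A.fasta	ExampleRT.B.fasta	ExampleRT.C.fasta
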