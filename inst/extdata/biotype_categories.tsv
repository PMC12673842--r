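biotype	category
protein_coding	protein_coding
lncRNA	lncRNA
retained_intron	retained_intron
nonsense_mediated_decay	nonsense_mediated_decay
protein_coding_CDS_not_defined	CDS_undefined
processed_transcript	CDS_undefined
non_stop_decay	nonsense_mediated_decay
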