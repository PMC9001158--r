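label_a	label_b	n
LESSONAE	LESSONAE	6
ESCULENTUS	ESCULENTUS	13
RR_GENOTYPE	RR_GENOTYPE	1
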