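label_a	label_b	n
LESSONAE	LESSONAE	6
LESSONAE	ESCULENTUS	11
LESSONAE	RR_GENOTYPE	1
ESCULENTUS	ESCULENTUS	2
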