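label_a	label_b	n
LESSONAE	LESSONAE	130
LESSONAE	ESCULENTUS	8
LESSONAE	RR_GENOTYPE	0
LESSONAE	UNIDENTIFIED	0
ESCULENTUS	LESSONAE	3
ESCULENTUS	ESCULENTUS	215
ESCULENTUS	RR_GENOTYPE	3
ESCULENTUS	UNIDENTIFIED	3
RR_GENOTYPE	LESSONAE	0
RR_GENOTYPE	ESCULENTUS	0
RR_GENOTYPE	RR_GENOTYPE	4
RR_GENOTYPE	UNIDENTIFIED	0
UNIDENTIFIED	LESSONAE	7
UNIDENTIFIED	ESCULENTUS	9
UNIDENTIFIED	RR_GENOTYPE	0
UNIDENTIFIED	UNIDENTIFIED	0
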