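species	type	id
mouse	false_positive	NAAC
mouse	false_positive	IODO
mouse	false_positive	NEDD
mouse	false_positive	COUM
mouse	false_positive	MALA
mouse	false_positive	PCNB
mouse	false_positive	DBET
mouse	false_negative	ADBQ
mouse	false_negative	MACR
mouse	false_negative	TDPP
mouse	false_negative	TFEL
human	false_positive	SNP_cervical
human	false_positive	SNP_endometrial
human	false_positive	SNP_esophageal
human	false_positive	SNP_gastric
human	false_positive	SNP_head_and_neck
human	false_positive	SNP_lung
human	false_positive	SNP_ovarian
human	false_positive	SNP_testicular
human	false_positive	SNP_lymphoma
human	false_positive	SNP_lymphoma_hodgkins
human	false_negative	GSE16415
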