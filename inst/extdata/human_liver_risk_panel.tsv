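id	group	risk_factor	label
GDS2239	expression	HCV	positive
GDS3347	expression	type_2_diabetes	positive
GDS3656	expression	type_1_diabetes	positive
GSE10356_AC	expression	alcoholic_cirrhosis	positive
GSE10356_HC	expression	HCV_cirrhosis	positive
GSE15331	expression	HCV	positive
GSE15653	expression	type_2_diabetes	positive
GSE16415	expression	type_2_diabetes	positive
GSE20948_12h	expression	HCV	positive
GSE20948_18h	expression	HCV	positive
GSE20948_24h	expression	HCV	positive
GSE20948_48h	expression	HCV	positive
GSE23343	expression	type_2_diabetes	positive
SNP_liver	polymorphism	liver_cancer	positive
SNP_bladder	polymorphism	bladder_cancer	negative
SNP_brain	polymorphism	brain_cancer	negative
SNP_breast	polymorphism	breast_cancer	negative
SNP_cancer	polymorphism	cancer_general	negative
SNP_cervical	polymorphism	cervical_cancer	negative
SNP_colorectal	polymorphism	colorectal_cancer	negative
SNP_endometrial	polymorphism	endometrial_cancer	negative
SNP_esophageal	polymorphism	esophageal_cancer	negative
SNP_gastric	polymorphism	gastric_cancer	negative
SNP_head_and_neck	polymorphism	head_and_neck_cancer	negative
SNP_lung	polymorphism	lung_cancer	negative
SNP_lymphoma	polymorphism	lymphoma	negative
SNP_lymphoma_hodgkins	polymorphism	lymphoma_hodgkins	negative
SNP_ovarian	polymorphism	ovarian_cancer	negative
SNP_pancreatic	polymorphism	pancreatic_cancer	negative
SNP_prostate	polymorphism	prostate_cancer	negative
SNP_renal	polymorphism	renal_cancer	negative
SNP_skin_non_melanoma	polymorphism	skin_non_melanoma_cancer	negative
SNP_testicular	polymorphism	testicular_cancer	negative
SNP_thyroid	polymorphism	thyroid_cancer	negative
SNP_leukemia	polymorphism	leukemia	negative
SNP_leukemia_childhood_all	polymorphism	leukemia_childhood_all	negative
SNP_alzheimers	polymorphism	alzheimers_disease	negative
SNP_schizophrenia	polymorphism	schizophrenia	negative
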