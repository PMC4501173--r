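family_id	id	father_id	mother_id	sex	birth_year	ovca_age	brca_age	status_age	vital	brca1_test	brca2_test	prs_value	proband	relation
ex1	mum	0	0	F	1915	60	NA	65	A	U	U	NA	0	mother
ex1	dad	0	0	M	1913	NA	NA	NA	U	U	U	NA	0	father
ex1	target	dad	mum	F	1940	NA	NA	50	A	N	N	NA	1	proband
ex1	sis	dad	mum	F	1942	45	NA	50	A	U	U	NA	0	sister
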