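characteristic	level	n	pct
diagnostic_age_years	30-50	13	17.6
diagnostic_age_years	>50	61	82.4
tumor_type	IDC	59	79.7
tumor_type	DCIS	5	6.8
tumor_type	ILC	3	4.1
tumor_type	PC	1	1.4
tumor_type	TC	3	4.1
tumor_type	MC	3	4.1
tumor_size	<2cm	32	43.2
tumor_size	2-5cm	37	50.0
tumor_size	>5cm	5	6.8
tumor_grade	I	15	20.3
tumor_grade	II	37	50.0
tumor_grade	III	22	29.7
axillary_lymph_node	Positive	29	39.1
axillary_lymph_node	Negative	40	54.0
axillary_lymph_node	Unknown	5	6.7
disease_stage	Stage1A	19	25.6
disease_stage	Stage1B	3	4.0
disease_stage	Stage2A	28	37.8
disease_stage	Stage2B	10	13.5
disease_stage	Stage3A	5	6.7
disease_stage	Stage3C	4	5.4
disease_stage	Unknown	5	6.7
estrogen_receptor	Positive	66	89.2
estrogen_receptor	Negative	7	9.5
estrogen_receptor	Unknown	1	1.4
progesterone_receptor	Positive	56	75.7
progesterone_receptor	Negative	17	23.0
progesterone_receptor	Unknown	1	1.4
her2_status	Positive	6	8.1
her2_status	Negative	67	90.5
her2_status	Unknown	1	1.4
birads_category	4B/C	40	54.1
birads_category	5C	33	44.6
birads_category	Unknown	1	1.4
clinical_relapse	Yes	8	10.8
clinical_relapse	No	64	86.5
clinical_relapse	Unknown	2	2.7
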