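kind	rule_id	input	expected	in_chem_group
rewrite	1	Failure, Renal	Renal Failure	FALSE
rewrite	1	Failure, Renal, Acute		FALSE
rewrite	1	Bandages, and dressings		FALSE
rewrite	2	Alzheimer's disease	Alzheimer disease	FALSE
rewrite	2	Crohn's	Crohn	FALSE
rewrite	2	disease		FALSE
rewrite	3	Selective Serotonin Reuptake Inhibitors (SSRIs)	Selective Serotonin Reuptake Inhibitors|SSRIs	FALSE
rewrite	3	Polibar Rapid (P/P)	Polibar Rapid|P/P	FALSE
rewrite	3	treatment of pain (MI)		FALSE
rewrite	4	Chondria <beetle>	Chondria	FALSE
rewrite	4	every <integer> weeks	every weeks	FALSE
rewrite	4	<only>		FALSE
rewrite	5	Surgical intervention (finding)	Surgical intervention	FALSE
rewrite	5	Heart (Body Part, Organ, or Organ Component)	Heart	FALSE
rewrite	5	Controls (Instrument)		FALSE
rewrite	6	(protein) methionine-R-sulfoxide reductase	methionine-R-sulfoxide reductase	FALSE
rewrite	6	(2-5')oligo(A) synthetase activity	oligo(A) synthetase activity	FALSE
rewrite	6	(S)-ibuprofen		TRUE
rewrite	7	[D]Respiratory abnormalities	Respiratory abnormalities	FALSE
rewrite	7	[M]Lymphoid leukaemias	Lymphoid leukaemias	FALSE
rewrite	7	[pyruvate dehydrogenase (lipoamide)] phosphatase activity	phosphatase activity	FALSE
rewrite	8	Controls (Instrument)	Controls	FALSE
rewrite	8	t(3;6)(p13;q25)	t(3;6)	FALSE
rewrite	8	flagellar filament (sensu Bacteria)	flagellar filament	FALSE
rewrite	9	Abstracts [Publication Type]	Abstracts	FALSE
rewrite	9	Shigella flexneri 2a [II:3,4]	Shigella flexneri 2a	FALSE
rewrite	9	Gluten-free foods [generic 1]	Gluten-free foods	FALSE
suppress	S1	10*9/L	suppressed	FALSE
suppress	S1	WHILE	suppressed	FALSE
suppress	S1	protein X	kept	FALSE
suppress	S2	Oxygen 2%	suppressed	FALSE
suppress	S2	Paracetamol 500 gram	suppressed	FALSE
suppress	S2	Vitamin B12	kept	FALSE
suppress	S3	ADHESIVE @@ BANDAGE	suppressed	FALSE
suppress	S3	bandage	kept	FALSE
suppress	S4	EC 2.7.1.112	suppressed	FALSE
suppress	S4	EC 2.7.1.-	suppressed	FALSE
suppress	S4	ECG 2.7	kept	FALSE
suppress	S5	Unclassified sequences	suppressed	FALSE
suppress	S5	Injury, NEC	suppressed	FALSE
suppress	S5	NECROSIS	kept	FALSE
suppress	S6	Other and unspecified leukaemia	suppressed	FALSE
suppress	S6	Anemia, NOS	suppressed	FALSE
suppress	S6	DIAGNOSIS	kept	FALSE
suppress	S7	Other	suppressed	FALSE
suppress	S7	Other diseases	suppressed	FALSE
suppress	S7	Mother	kept	FALSE
suppress	S8	Head and Neck Squamous Cell Carcinoma	suppressed	FALSE
suppress	S8	insulin-like growth factor binding protein 1	suppressed	FALSE
suppress	S8	Head and Neck Squamous Cell Carcinoma	kept	TRUE
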