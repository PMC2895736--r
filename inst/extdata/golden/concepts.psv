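C0000001|ENG|S0000001|N|Failure, Renal|
C0000002|ENG|S0000002|N|Alzheimer's disease|
C0000003|ENG|S0000003|N|Crohn's|
C0000004|ENG|S0000004|N|Selective Serotonin Reuptake Inhibitors (SSRIs)|
C0000005|ENG|S0000005|N|Polibar Rapid (P/P)|
C0000006|ENG|S0000006|N|Chondria <beetle>|
C0000007|ENG|S0000007|N|every <integer> weeks|
C0000008|ENG|S0000008|N|Surgical intervention (finding)|
C0000009|ENG|S0000009|N|Heart (Body Part, Organ, or Organ Component)|
C0000010|ENG|S0000010|N|(protein) methionine-R-sulfoxide reductase|
C0000011|ENG|S0000011|N|(2-5')oligo(A) synthetase activity|
C0000012|ENG|S0000012|N|[D]Respiratory abnormalities|
C0000013|ENG|S0000013|N|[M]Lymphoid leukaemias|
C0000014|ENG|S0000014|N|[pyruvate dehydrogenase (lipoamide)] phosphatase activity|
C0000015|ENG|S0000015|N|Controls (Instrument)|
C0000016|ENG|S0000016|N|t(3;6)(p13;q25)|
C0000017|ENG|S0000017|N|flagellar filament (sensu Bacteria)|
C0000018|ENG|S0000018|N|Abstracts [Publication Type]|
C0000019|ENG|S0000019|N|Shigella flexneri 2a [II:3,4]|
C0000020|ENG|S0000020|N|Gluten-free foods [generic 1]|
C0000021|ENG|S0000021|N|10*9/L|
C0000022|ENG|S0000022|N|WHILE|
C0000023|ENG|S0000023|N|Oxygen 2%|
C0000024|ENG|S0000024|N|ADHESIVE @@ BANDAGE|
C0000025|ENG|S0000025|N|EC 2.7.1.112|
C0000026|ENG|S0000026|N|EC 2.7.1.-|
C0000027|ENG|S0000027|N|Unclassified sequences|
C0000028|ENG|S0000028|N|Injury, NEC|
C0000029|ENG|S0000029|N|Other and unspecified leukaemia|
C0000030|ENG|S0000030|N|Anemia, NOS|
C0000031|ENG|S0000031|N|Other|
C0000032|ENG|S0000032|N|Other diseases|
C0000033|ENG|S0000033|N|Head and Neck Squamous Cell Carcinoma|
C0000034|ENG|S0000034|N|insulin-like growth factor binding protein 1|
C0000035|ENG|S0000035|N|(S)-ibuprofen|
C0000036|ENG|S0000036|N|treatment of pain (MI)|
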