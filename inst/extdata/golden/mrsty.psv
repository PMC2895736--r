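C0000001|T033||Finding||
C0000002|T033||Finding||
C0000003|T033||Finding||
C0000004|T033||Finding||
C0000005|T033||Finding||
C0000006|T033||Finding||
C0000007|T033||Finding||
C0000008|T033||Finding||
C0000009|T033||Finding||
C0000010|T033||Finding||
C0000011|T033||Finding||
C0000012|T033||Finding||
C0000013|T033||Finding||
C0000014|T033||Finding||
C0000015|T033||Finding||
C0000016|T033||Finding||
C0000017|T033||Finding||
C0000018|T033||Finding||
C0000019|T033||Finding||
C0000020|T033||Finding||
C0000021|T033||Finding||
C0000022|T033||Finding||
C0000023|T033||Finding||
C0000024|T033||Finding||
C0000025|T033||Finding||
C0000026|T033||Finding||
C0000027|T033||Finding||
C0000028|T033||Finding||
C0000029|T033||Finding||
C0000030|T033||Finding||
C0000031|T033||Finding||
C0000032|T033||Finding||
C0000033|T033||Finding||
C0000034|T033||Finding||
C0000035|T121||Pharmacologic Substance||
C0000036|T033||Finding||
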