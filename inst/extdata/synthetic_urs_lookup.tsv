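normalized_id	urs_taxid
hsa-mir-21	URS00000001A1_9606
hsa-mir-155	URS00000002B2_9606
hsa-let-7a	URS00000003C3_9606
mmu-mir-21	URS00000004D4_10090
dre-mir-430a	URS00000005E5_7955
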