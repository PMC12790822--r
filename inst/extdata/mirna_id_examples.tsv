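text	should_match	scheme	normalized_id
hsa-miR-21	yes	mirbase	hsa-mir-21
hsa-miR-21-5p	yes	mirbase	hsa-mir-21
hsa-miR-21-3p	yes	mirbase	hsa-mir-21
hsa-let-7a	yes	mirbase	hsa-let-7a
hsa-let-7a-1	yes	mirbase	hsa-let-7a-1
mmu-mir-155	yes	mirbase	mmu-mir-155
dre-miR-430a	yes	mirbase	dre-mir-430a
cel-lin-4	yes	mirbase	cel-lin-4
Hsa-Mir-21	yes	mirgenedb	hsa-mir-21
Hsa-Mir-17-P1	yes	mirgenedb	hsa-mir-17-p1
Hsa-Mir-21_pre	yes	mirgenedb	hsa-mir-21
Hsa-Let-7-P1_5p	yes	mirgenedb	hsa-let-7-p1
microRNA	no	NA	NA
miR-21	no	NA	NA
microRNAs are small RNAs	no	NA	NA
the let-down effect	no	NA	NA
miRNA-21	no	NA	NA
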