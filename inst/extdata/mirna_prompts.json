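{
  "binding_filter": "Does the paper describe experiments investigating direct binding between a miRNA and an mRNA (for example reporter assays, immunoprecipitation, pull-down, or CRISPR deletion of a miRNA response element)? Papers that only report differential expression, in-silico target prediction, or pathway analysis do not qualify. Answer yes or no.",
  "cluster_filter": "Is the paper primarily a study of a miRNA cluster, i.e. a set of co-transcribed (polycistronic) miRNAs acting in concert? Cluster studies require different treatment and must not be curated with this flowchart. Answer yes or no.",
  "reporter_assay": "Does the paper have a functional interaction between the miRNA and an mRNA, determined by a reporter assay? Acceptable assays include: Luciferase reporter assays where a luciferase reporter gene is fused to the 3'UTR of the target mRNA; and CRISPR/CAS9 deletion of the miRNA response element with subsequent measurement of protein levels. Answer yes or no.",
  "mrna_level": "Does the paper show that the level of the target mRNA decreases in response to the miRNA, measured by qRT-PCR or an equivalent mRNA quantification assay? A decrease in target mRNA level indicates silencing by mRNA destabilization. Answer yes or no.",
  "protein_level": "Does the paper show that the target protein level decreases in response to the miRNA (for example by western blot) while the target mRNA level is unchanged? This combination indicates silencing by inhibition of translation. Answer yes or no.",
  "t_destabilization": "Terminal: annotate miRNA-mediated gene silencing by mRNA destabilization (GO:0035279) with the MF co-term GO:1903231.",
  "t_translation": "Terminal: annotate miRNA-mediated gene silencing by inhibition of translation (GO:0035278) with the MF co-term GO:1903231.",
  "t_general": "Terminal: annotate miRNA-mediated post-transcriptional gene silencing (GO:0035195) with the MF co-term GO:1903231."
}
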