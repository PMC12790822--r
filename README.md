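# mirflow

Flowchart-guided curation of the miRNA gene-silencing literature.

Biocuration of miRNA-mediated post-transcriptional gene silencing follows a
standardized Gene Ontology (GO) decision procedure: from the experiments a
paper reports, decide whether a miRNA functionally silences a target mRNA
and by which mechanism, then annotate one of three Biological Process
terms — GO:0035195 (the parent, mechanism unresolved), GO:0035278
(inhibition of translation) or GO:0035279 (mRNA destabilization) — together
with the Molecular Function co-term GO:1903231, anchored on the miRNA's
RNAcentral `URS_taxid` and the validated target's UniProtKB accession.

`mirflow` executes that procedure mechanically over JATS full-text XML.
A curation flowchart (typed DAG of filter/decision/terminal nodes, loaded
from JSON with per-node prompts) is traversed one constrained yes/no
question at a time; every answer is produced by a **backend** satisfying a
verified constrained-generation contract — selections must come from the
offered option list, evidence spans must be verbatim source substrings with
0-based half-open offsets, reasoning is capped at 1024 tokens per request.
The result of each run is an auditable `curation_record` (per-node answers,
reasoning traces, evidence spans that re-validate byte-exactly), exportable
as JSONL, GPAD 2.0 and a reviewer-question export. Two deterministic
model-free backends (scripted, keyword-rule) make the whole pipeline
testable without GPU inference; a constrained-decoding model adapter can
plug in behind the same contract.

The package also ships the surrounding tooling: miRBase/MirGeneDB
identifier detection and single-miRNA/review/retraction corpus filters,
EuropePMC-style gene-mention target resolution with `DONE`/`NOT_IN_LIST`
sentinels, token-budgeted lazy section loading with backend-arbitrated
heading normalization, and a synthetic JATS corpus generator with known
ground truth that serves as the test bed for everything else.

## Worked example

Generate a synthetic destabilization article, curate it with the keyword
backend, and export GPAD:

```r
library(mirflow)

fc <- mirna_flowchart()
entry <- generate_article(synth_spec("term_0035279", seed = 7,
                                     mirna_id = "hsa-mir-21",
                                     targets = c("PTEN", "SMAD4")))
article <- parse_jats(entry$xml)
urs <- load_urs_lookup(system.file("extdata", "synthetic_urs_lookup.tsv",
                                   package = "mirflow"))
uni <- load_uniprot_lookup(system.file("extdata", "synthetic_uniprot_lookup.tsv",
                                       package = "mirflow"))

record <- curate_article(article, fc, keyword_backend(),
                         parse_gene_list(entry$mentions), urs, uni)
record
#> <curation_record> PMC1000007 [annotated] 4 decision(s), 4 annotation(s)

tidy(record)
#> # A tibble: 4 × 5
#>   node_id        answer reasoning_tokens has_evidence evidence_span
#>   <chr>          <chr>             <int> <lgl>        <chr>
#> 1 binding_filter yes                   7 FALSE        <NA>
#> 2 cluster_filter no                    7 FALSE        <NA>
#> 3 reporter_assay yes                   7 TRUE         Luciferase reporter assay…
#> 4 mrna_level     yes                   8 TRUE         qRT-PCR analysis showed t…
```

The record reached the mRNA-destabilization terminal in four steps: the
binding-experiment triage passed, the cluster triage passed, the luciferase
3'UTR reporter assay established the functional interaction, and the
qRT-PCR mRNA decrease selected GO:0035279 over the translation-inhibition
branch. Both evidence rows are verbatim quotes from the article's Results
section, re-validated against stored offsets. Four annotations result
(2 GO terms × 2 validated targets):

```r
write_gpad(list(record), "demo.gpad")
readLines("demo.gpad")[3]
#> URS00000001A1_9606\t\tRO:0002331\tGO:0035279\tPMID:30000007\tECO:0000501\t\t\t2026-09-23\tmirflow\tRO:0002233(UniProtKB:P90001)\t
```

The subject is the miRNA's URS_taxid, the relation is involved-in for the
BP term, the evidence type marks an automatic assertion (all output is
candidate annotation pending human review), and the target travels as a
has-input annotation extension. `summarize_run()`, `export_review()` and
`glance()`/`autoplot()` provide corpus-level tallies, the reviewer export
(four standard questions per annotated record) and quick summaries.

A thin command-line wrapper covers the same flows
(`exec/mirflow validate-flowchart|inspect-article|filter|synth|curate`).

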