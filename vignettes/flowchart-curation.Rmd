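---
title: "Flowchart-guided curation of miRNA gene-silencing literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowchart-guided curation of miRNA gene-silencing literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflow)
```

## The curation problem

Gene Ontology (GO) curation of miRNA-mediated gene silencing is narrow and
procedural: curators decide, from the experiments a paper reports, whether a
miRNA functionally silences a target mRNA and by which mechanism, and then
annotate one of three Biological Process terms —

* **GO:0035195** — miRNA-mediated post-transcriptional gene silencing (the
  parent term, used when the mechanism is unresolved),
* **GO:0035278** — silencing by inhibition of translation,
* **GO:0035279** — silencing by mRNA destabilization,

each accompanied by the Molecular Function co-term **GO:1903231** (mRNA
base-pairing post-transcriptional repressor activity). GO consortium guidance
expresses this decision procedure as a flowchart of yes/no questions over
evidence classes: did a luciferase 3'UTR reporter assay (or CRISPR deletion
of the miRNA response element) demonstrate a functional interaction; did the
target mRNA level fall (qRT-PCR); did the protein fall while the mRNA was
unchanged (western blot). Because the evidence requirements are narrowly
defined, the procedure can be executed mechanically — by a language model
answering one constrained question per node — provided every step is
auditable afterwards.

`mirflow` implements that execution engine. Its design premise is strict
separation between the *deterministic* machinery (flowchart traversal,
context budgeting, evidence offset bookkeeping, identifier resolution,
serialization) and the *oracle* answering the questions (the backend). The
machinery is what this package tests; the backend contract is what a real
reasoning model must satisfy to plug in.

## The flowchart model

A flowchart is a typed DAG of nodes:

* **filter** nodes are cheap triage (two ship in the bundled fixture:
  "does the paper mention binding experiments at all?" and "is this a
  miRNA-cluster study?" — cluster studies need different treatment because
  the co-transcribed miRNAs act in concert, and are excluded);
* **decision** nodes are the evidence questions proper;
* **terminal** nodes carry the (GO term, aspect) payload to annotate.

Each filter/decision branch either names a successor node or falls through
to an `on_fail` disposition: `filtered` (triage rejection) or
`no_annotation` (evidence insufficient). The local `is_a` hierarchy of the
payload terms is stored with the flowchart so the engine can verify
*specificity*: a finalized record must never claim the bare parent term
when its recorded answers satisfy a child-term path. That check exists
because annotation to the parent is technically "accurate" under the GO
hierarchy even where a mechanism-specific term is warranted, and a silent
under-annotation would be invisible downstream.

The bundled fixture (`mirna_flowchart()`) is a **reconstruction** of the GO
wiki's miRNA guidance from its published textual description — the original
figure is an image with no machine-readable form — and is documented as
such. The node inventory follows the evidence classes the guidance names:
binding-experiment triage, cluster triage, reporter-assay gate, an
mRNA-level decision separating destabilization, and a protein-level
decision separating translational inhibition from the unresolved parent
outcome. The MF co-term is attached to every terminal (configurable per
terminal in the JSON): most silencing annotations carry it, and making it
unconditional keeps the fixture simple without losing generality.

```{r}
fc <- mirna_flowchart()
tidy(fc)
```

`enumerate_paths()` unrolls the full decision tree and is the traversal
oracle: iterating `flow_step()` over any complete answer vector must reach
the same outcome, a property the test suite checks against a second,
independently coded recursive enumerator on hundreds of randomized
flowcharts (up to 12 decision nodes, the scale of realistic curation
charts).

## The backend contract

Backends answer two request shapes, and the engine trusts neither:

* **constrained choice** — select exactly one of a fixed option list
  ("yes"/"no" at flowchart nodes; real headings plus `NONE` for section
  mapping; gene symbols plus `DONE`/`NOT_IN_LIST` for target selection). A
  response outside the option list is a contract violation and raises; it
  is never repaired, because silent repair would launder a model failure
  into a curation decision.
* **constrained span** — return a passage with 0-based half-open character
  offsets into the supplied source text. The verifier re-slices the source
  and rejects anything that is not byte-identical, so stored evidence is
  *guaranteed* to be a verbatim quote of the article. Offsets are
  re-validated again at record level (`validate_record_evidence()`).

Reasoning traces accompany every response, capped at **1024 reasoning
tokens** per request (the default `reasoning_cap`) — a budget that
reasoning models rarely exhaust on questions this narrow — and stored
verbatim and uncapped in the record, because the trace is the artefact a
human reviewer audits. Temperature defaults to 0: constrained decoding
with greedy sampling makes a model backend a pure function of the prompt,
which is what makes record replay meaningful.

Two model-free backends ship with the package. The **scripted backend**
answers from an explicit per-key script and fails loudly on any unscripted
key; it is the replay vehicle (`record_backend()` turns any record back
into its generating script) and the adversarial-testing vehicle (scripts
can lie about spans, and the verifier must catch them). The **keyword
backend** is an ordered rule table keyed to the assay vocabulary of the
synthetic corpus; it stands in for a reasoning model so that end-to-end
tests measure engine plumbing, not language understanding. Rules match
against the article text portion of the prompt only — node prompts
themselves name the acceptable assays, and an instruction must not
self-trigger a rule. A real constrained-decoding adapter (llama.cpp-class,
local weights) plugs in behind the same contract; API-hosted models cannot,
because constrained decoding requires control of token sampling. No such
adapter is bundled: the package is deliberately runnable without GPU
inference.

## Articles, sections and budgets

Articles arrive as JATS/EuropePMC full-text XML. `parse_jats()` flattens
each top-level `<sec>` to plain text (NFC-normalized, space runs collapsed,
paragraph breaks kept as single newlines — offsets into this text must be
stable, so normalization happens exactly once, at parse time) and keeps
headings verbatim. Heading variability ("MATERIALS AND METHODS",
"Findings", ...) is resolved by a zero-shot constrained choice per
canonical label over the article's *actual* headings plus `NONE`; the core
contains no string-similarity fallback, so the mapping is exactly as good
as the backend and fully scriptable in tests. The abstract travels as its
own field and maps deterministically. A heading claimed by one label is
withheld from later labels, making the index injective by construction.

Context is budgeted: a run may charge at most `max_context_tokens`
(default 64 000, the context that fits single-accelerator inference for
32B-class models) and sections load lazily — the first request for a
canonical section charges its token count, later requests hit the cache.
Truncation respects paragraph boundaries (greedy packing). Evidence-span
sources are additionally capped at `max_evidence_source_tokens` (default
4 000) because substring-constrained decoding over long sources is the
expensive operation in real backends; the documented consequence, visible
in the record, is that evidence for a decision can only come from the
hinted section's loaded prefix. The token counter is pluggable and
defaults to whitespace word counts: budgets in a model-free test rig need
a model-free, deterministic counter; adapters for real tokenizers can
substitute theirs.

When a hinted section is absent, the run falls back (abstract, then full
body — configurable) and flags the fallback in the load log rather than
silently returning nothing: missing-evidence failures must surface in
review, not be masked upstream.

## Corpus filters and identifier resolution

Only single-miRNA primary research articles are curable with this
flowchart. `detect_mirna_ids()` ships documented, deliberately strict
patterns for the two naming authorities (miRBase `hsa-miR-21-5p`-style and
MirGeneDB `Hsa-Mir-21`-style, case-disjoint by design); detection of such
an identifier is what licenses the link to an RNAcentral `URS_taxid`.
Distinctness is counted at the miRNA *gene* level: `-5p`/`-3p` arms and
case collapse, paralog suffixes do not (`hsa-miR-21-5p` ≡ `hsa-miR-21-3p`;
`hsa-let-7a-1` ≢ `hsa-let-7a-2`). Arm handling is a genuine open point in
the field's counting conventions; the package picks gene-level and
documents it rather than guessing what any particular pipeline did.
Reviews and retracted publications are excluded on publication-type
markers and retraction-notice links. The normative fixture
`mirna_id_examples.tsv` pins the patterns' positive and negative cases.

Target genes are resolved against the EuropePMC annotations-API mention
list for the article rather than free-text extraction: span extraction
does not reliably end at symbol boundaries, and a closed candidate list
makes selection constrainable. The selection loop offers the not-yet-chosen
symbols plus `DONE` and `NOT_IN_LIST` each round, keeps at most
`max_targets` (default 4 — complete recoveries in practice range from one
to four targets per article), and treats `NOT_IN_LIST` as an explicit
unresolvable outcome: when the true target is missing from the mention
list the backend must be able to say so instead of being forced onto a
wrong symbol. Symbols map to UniProtKB accessions by exact
(symbol, taxon) lookup, the taxon taken from the miRNA's URS suffix; a
miss keeps the bare symbol and flags it. The bundled lookup tables are
synthetic stand-ins (named `synthetic_*`) sufficient for the generator's
identifier pool; production use supplies real RNAcentral/UniProt dumps in
the same two/three-column TSV shapes.

## Records, outputs and review

Every run yields a `curation_record`: ordered per-node decisions (prompt
used, answer, reasoning, evidence span with offsets), heading choices,
target-selection rounds, status (`annotated`, `filtered`,
`no_annotation`, `error`) and run metadata (flowchart version, backend
name, config hash, timestamp). Records are the audit artefact — curation
traditionally leaves no decision trail, and the record is precisely that
trail. Three invariants are enforced rather than assumed: decisions replay
through the flowchart to the recorded outcome (checked at finalization,
where the specificity error is raised); evidence spans re-slice
byte-identically from the stored section text; and zero validated targets
demotes the record to `no_annotation` with a note instead of emitting a
target-less annotation, because these annotations are
(miRNA, GO term, target) triples.

Outputs: JSONL for records (lossless round-trip), **GPAD 2.0** for
annotations (12 tab-separated columns; subject is the `URS_taxid`;
relations default to `RO:0002331` involved-in for BP and `RO:0002327`
enables for MF; evidence type defaults to `ECO:0000501`, evidence used in
automatic assertion, because GO policy does not admit unreviewed
model-derived annotations — everything this package emits is a *candidate*
pending human review; the target gene travels as an annotation extension
under `RO:0002233` has-input). The GPAD column mapping for the target is a
package decision — the triple itself does not dictate one — and all ids are
configurable via `mirflow_config()`. A shipped line validator
(`validate_gpad_line()`) checks every emitted line; a record missing its
URS or PMID is skipped with a warning, never written malformed. The
reviewer export renders each annotated record's trace with the four
standard reviewer questions (reasoning addressed? evidence supports?
annotation correct? targets correct?) pre-filled unanswered, as
tool-agnostic JSONL for whatever review platform hosts the evaluation.

## The synthetic corpus

`generate_article()` and `generate_corpus()` produce JATS articles whose
curation outcome is known by construction. Each outcome class embeds a
fixed keyword vocabulary mirroring the real evidence classes:

| outcome | embedded signal |
|---|---|
| `filtered_no_binding` | expression/in-silico phrasing only, no binding assay |
| `filtered_cluster` | polycistronic-cluster phrasing |
| `no_annotation` | immunoprecipitation/pull-down binding but no reporter assay |
| `term_0035279` | luciferase 3'UTR sentences + qRT-PCR mRNA-decrease |
| `term_0035278` | luciferase + western-blot protein decrease, mRNA unchanged |
| `term_0035195` | luciferase only, mechanism not examined |

plus corpus-filter exclusion classes (`multi_mirna`, `review`,
`retracted`, `no_mirna`) wrapping an otherwise curable body. Articles
carry a miRBase identifier from a small pool matched to the synthetic URS
table, 1–4 validated targets, decoy genes mentioned *without* validation
phrasing, one of three heading styles (canonical, upper-case, exotic) to
exercise heading normalization, and a matching EuropePMC-shape mention
payload (targets ∪ decoys). Composition over a corpus is exact by
largest-remainder apportionment with ties to the first-listed outcome, and
every sample derives from the article seed, so equal seeds give
byte-identical corpora.

What the generator deliberately does **not** emulate: realistic prose,
figures and tables (real assay results often live in graphs that require
interpretation), supplementary materials (a known real-world failure mode:
mandatory qRT-PCR results reported only in supplements are invisible to a
text pipeline — reproduced here only as the absent-evidence case), and
linguistic ambiguity. A 100% pass rate on this corpus therefore certifies
the *engine* — traversal, budgeting, provenance, resolution,
serialization — not any model's reading comprehension.

## Numerical and design choices

* Problem sizes in the shipped checks: 200 randomized flowcharts for
  traversal-oracle equivalence; 20 seeds × 100-article corpora (2 000
  curations) for end-to-end recovery; 20 seeds × 100 for corpus-filter
  exactness. These sizes cover every outcome class many times over at
  desk scale.
* Determinism: all constrained calls run at temperature 0; record replay
  through `record_backend()` must reproduce the record byte-identically
  modulo timestamp.
* Tie-breaks: flowchart edges are binary, so traversal needs none; keyword
  rule order is semantics (first match wins); apportionment ties go to the
  first-listed outcome.
* Degenerate inputs: a single-terminal flowchart is valid (one empty
  path); empty corpora and empty record sets serialize to valid empty
  outputs; a 0-token-fitting section loads a word-truncated first
  paragraph rather than nothing.
* Evidence capture happens at decision nodes only — filters are cheap
  triage and their yes/no is cheap to re-derive, while decision evidence
  is what reviewers audit.

## Limitations

The headline performance figures of model-driven curation (term
correctness, reasoning agreement, throughput on the open-access
literature) are properties of a specific reasoning model on real papers
and are not measurable in this package's model-free test rig; what the
package certifies is that every deterministic component around the model
is exact. Cluster curation is out of scope by design. Only open-access,
text-extractable evidence is reachable; PDF parsing, figures and
supplementary files are not consumed. The bundled flowchart covers three
BP terms and one MF term — a deliberately tiny, high-precision slice of GO.
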