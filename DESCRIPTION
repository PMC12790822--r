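Package: mirflow
Title: Flowchart-Guided Curation of miRNA Gene-Silencing Literature
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executes expert Gene Ontology (GO) curation flowcharts over
    full-text articles through a constrained language-model backend contract,
    producing candidate GO annotations for miRNA-mediated gene silencing
    (GO:0035195 and its mechanism-specific children) together with auditable
    per-node reasoning traces and verbatim evidence spans. Includes a JATS XML
    article store with lazy, token-budgeted section loading; miRBase/MirGeneDB
    identifier detection and corpus filters; deterministic scripted and
    keyword-rule backends for model-free testing; EuropePMC-style gene-mention
    target resolution; GPAD 2.0, JSONL and reviewer exports; and a synthetic
    JATS corpus generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    jsonlite,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    xml2
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
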