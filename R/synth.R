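#' Synthetic JATS corpus with known ground truth
#'
#' Generates JATS-sectioned articles whose curation outcome is known by
#' construction: each outcome class embeds a fixed, documented keyword
#' vocabulary (luciferase 3'UTR reporter phrasing for functional
#' interaction; qRT-PCR mRNA-decrease phrasing for destabilization;
#' western-blot protein-decrease with unchanged mRNA for translational
#' inhibition; polycistronic-cluster phrasing for cluster triage) that the
#' default keyword backend recognises unambiguously — so end-to-end tests
#' measure engine plumbing, not language understanding. Articles carry real
#' miRBase-style identifiers, decoy gene mentions without validation
#' phrasing, varied heading styles to exercise zero-shot heading
#' normalization, and a matching EuropePMC-shape gene mention payload.
#'
#' @name synth-corpus
NULL

SYNTH_OUTCOMES <- c("filtered_no_binding", "filtered_cluster", "no_annotation",
                    "term_0035195", "term_0035278", "term_0035279")
SYNTH_EXCLUSIONS <- c("multi_mirna", "review", "retracted", "no_mirna")

SYNTH_MIRNAS <- list(
  list(raw = "hsa-miR-21", norm = "hsa-mir-21", taxon = "9606"),
  list(raw = "hsa-miR-155", norm = "hsa-mir-155", taxon = "9606"),
  list(raw = "hsa-let-7a", norm = "hsa-let-7a", taxon = "9606"),
  list(raw = "mmu-miR-21", norm = "mmu-mir-21", taxon = "10090"),
  list(raw = "dre-miR-430a", norm = "dre-mir-430a", taxon = "7955")
)
SYNTH_TARGET_POOL <- c("PTEN", "SMAD4", "TP53", "CDKN1A", "BCL2", "VEGFA",
                       "STAT3", "KRAS")
SYNTH_DECOY_POOL <- c("GAPDH", "ACTB", "DDX5", "EEF2", "RPL13A")

HEADING_STYLES <- list(
  canonical = c(introduction = "Introduction", methods = "Methods",
                results = "Results", discussion = "Discussion"),
  shouty = c(introduction = "INTRODUCTION", methods = "MATERIALS AND METHODS",
             results = "RESULTS", discussion = "DISCUSSION"),
  exotic = c(introduction = "Background", methods = "Experimental Procedures",
             results = "Findings", discussion = "Concluding Remarks")
)

# run code under a seeded RNG without disturbing the caller's RNG state
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify one synthetic article
#'
#' @param outcome One of the six flowchart outcomes
#'   (`filtered_no_binding`, `filtered_cluster`, `no_annotation`,
#'   `term_0035195`, `term_0035278`, `term_0035279`) or a corpus-filter
#'   exclusion class (`multi_mirna`, `review`, `retracted`, `no_mirna`).
#' @param seed Integer; fixes all sampling for this article.
#' @param mirna_id Normalized miRNA id from the built-in pool, or `NULL` to
#'   sample one.
#' @param targets Character vector of 1-4 validated target symbols, or
#'   `NULL` to sample.
#' @param decoys Character vector of decoy gene symbols, or `NULL` to
#'   sample.
#' @param heading_style `"canonical"`, `"shouty"` or `"exotic"`, or `NULL`
#'   to sample.
#' @param pmcid,pmid Identifiers (defaults derived from the seed).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(outcome, seed, mirna_id = NULL, targets = NULL,
                       decoys = NULL, heading_style = NULL,
                       pmcid = NULL, pmid = NULL) {
  outcome <- match.arg(outcome, c(SYNTH_OUTCOMES, SYNTH_EXCLUSIONS))
  seed <- as.integer(seed)
  with_rng(seed, {
    if (is.null(mirna_id)) {
      mirna_id <- SYNTH_MIRNAS[[sample.int(length(SYNTH_MIRNAS), 1)]]$norm
    }
    if (is.null(targets)) {
      n_targets <- sample.int(4, 1)
      targets <- sample(SYNTH_TARGET_POOL, n_targets)
    }
    if (is.null(decoys)) {
      decoys <- sample(SYNTH_DECOY_POOL, 2)
    }
    if (is.null(heading_style)) {
      heading_style <- sample(names(HEADING_STYLES), 1)
    }
  })
  annotated <- outcome %in% c("term_0035195", "term_0035278", "term_0035279")
  if (annotated && length(targets) == 0) {
    abort("contradictory spec: an annotated outcome needs at least one target")
  }
  if (length(targets) > 4) abort("at most 4 targets per article")
  if (length(intersect(targets, decoys)) > 0) {
    abort("decoys must not overlap targets")
  }
  pub_type <- switch(outcome, review = "review-article",
                     retracted = "retracted-publication", "research-article")
  structure(
    list(outcome = outcome, seed = seed, mirna_id = mirna_id,
         targets = targets, decoys = decoys, heading_style = heading_style,
         pub_type = pub_type,
         pmcid = pmcid %||% sprintf("PMC%07d", 1000000L + (seed %% 8999999L)),
         pmid = pmid %||% as.character(30000000L + (seed %% 9999999L))),
    class = "synth_spec"
  )
}

synth_mirna_info <- function(norm_id) {
  for (m in SYNTH_MIRNAS) if (identical(m$norm, norm_id)) return(m)
  abort(sprintf("miRNA '%s' is not in the synthetic pool", norm_id))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

synth_results_sentences <- function(spec, mirna_raw) {
  t1 <- spec$targets[1]
  luc <- vapply(spec$targets, function(g) sprintf(
    "Luciferase reporter assays showed that %s directly targets the 3'UTR of %s, reducing reporter activity.",
    mirna_raw, g), character(1))
  qpcr <- vapply(spec$targets, function(g) sprintf(
    "qRT-PCR analysis showed that %s mRNA levels decreased significantly after %s overexpression.",
    g, mirna_raw), character(1))
  wb <- vapply(spec$targets, function(g) sprintf(
    "Western blot analysis showed that %s protein levels were markedly reduced after %s overexpression, while qRT-PCR showed that %s mRNA levels remained unchanged.",
    g, mirna_raw, g), character(1))
  switch(
    spec$outcome,
    filtered_no_binding = sprintf(
      "Differential expression analysis identified %s as a putative target of %s. In-silico target prediction and pathway analysis supported this association.",
      t1, mirna_raw),
    no_annotation = sprintf(
      "RNA immunoprecipitation and biotin pull-down assays indicated direct binding of %s to the %s transcript. No functional readout of the interaction was measured.",
      mirna_raw, t1),
    filtered_cluster = paste(
      paste(luc, collapse = " "),
      "These experiments indicate that the locus is transcribed as a polycistronic miRNA cluster whose members act in concert."),
    term_0035279 = paste(c(luc, qpcr), collapse = " "),
    term_0035278 = paste(c(luc, wb), collapse = " "),
    term_0035195 = paste(
      paste(luc, collapse = " "),
      sprintf("These data indicate that %s silences %s expression, although the mechanism of repression was not examined further.",
              mirna_raw, t1)),
    # exclusion classes reuse the destabilization body
    paste(c(luc, qpcr), collapse = " ")
  )
}

synth_answers <- function(outcome) {
  switch(
    outcome,
    filtered_no_binding = c(binding_filter = "no"),
    filtered_cluster = c(binding_filter = "yes", cluster_filter = "yes"),
    no_annotation = c(binding_filter = "yes", cluster_filter = "no",
                      reporter_assay = "no"),
    term_0035279 = c(binding_filter = "yes", cluster_filter = "no",
                     reporter_assay = "yes", mrna_level = "yes"),
    term_0035278 = c(binding_filter = "yes", cluster_filter = "no",
                     reporter_assay = "yes", mrna_level = "no",
                     protein_level = "yes"),
    term_0035195 = c(binding_filter = "yes", cluster_filter = "no",
                     reporter_assay = "yes", mrna_level = "no",
                     protein_level = "no"),
    NULL
  )
}

synth_expected <- function(spec) {
  terms <- switch(spec$outcome,
                  term_0035195 = c("GO:0035195", "GO:1903231"),
                  term_0035278 = c("GO:0035278", "GO:1903231"),
                  term_0035279 = c("GO:0035279", "GO:1903231"),
                  character())
  status <- switch(spec$outcome,
                   filtered_no_binding = "filtered",
                   filtered_cluster = "filtered",
                   no_annotation = "no_annotation",
                   term_0035195 = , term_0035278 = , term_0035279 = "annotated",
                   "filtered")
  reasons <- switch(spec$outcome,
                    multi_mirna = "multiple_mirnas",
                    review = "review_article",
                    retracted = "retracted",
                    no_mirna = "no_mirna",
                    character())
  list(
    status = status,
    go_terms = terms,
    targets = if (status == "annotated") unname(spec$targets) else character(),
    filter_reasons = reasons,
    answers = synth_answers(spec$outcome)
  )
}

#' Generate one synthetic JATS article
#'
#' Deterministic for a fixed spec: the same spec yields byte-identical XML.
#'
#' @param spec A [synth_spec()].
#' @return A list:
#'   * `xml` — the JATS article as a single string;
#'   * `ground_truth` — expected status, GO terms, targets, corpus-filter
#'     reasons, and the answer vector realizing the outcome;
#'   * `mentions` — a EuropePMC-annotations-shaped payload (targets and
#'     decoys in first-appearance order);
#'   * `spec` — the input spec.
#' @export
generate_article <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  m <- synth_mirna_info(spec$mirna_id)
  mirna_raw <- if (spec$outcome == "no_mirna") "the microRNA under study" else m$raw
  headings <- HEADING_STYLES[[spec$heading_style]]
  t1 <- spec$targets[1]

  title <- if (spec$outcome == "no_mirna") {
    sprintf("MicroRNA-mediated regulation of %s in disease models", t1)
  } else {
    sprintf("%s regulates %s in disease models", m$raw, t1)
  }
  extra_mirna <- if (spec$outcome == "multi_mirna") {
    alt <- SYNTH_MIRNAS[[if (identical(m$norm, "hsa-mir-155")) 1L else 2L]]
    sprintf(" We additionally examined %s in the same system.", alt$raw)
  } else ""
  abstract <- paste0(
    sprintf("We investigated the role of %s in regulating %s.",
            mirna_raw, paste(spec$targets, collapse = ", ")),
    extra_mirna,
    " The regulatory mechanism was characterised in cell culture models.")

  intro <- sprintf(
    "Post-transcriptional regulation by microRNAs shapes gene expression programmes. Here we focus on the interaction between %s and %s.",
    mirna_raw, t1)
  methods <- "Cells were cultured under standard conditions and transfected with mimics or controls. Gene expression was quantified with standard molecular assays. Statistical analysis used two-sided tests."
  results_main <- synth_results_sentences(spec, mirna_raw)
  results_decoy <- sprintf(
    "Expression of %s was also profiled across the cohort as part of the wider screen.",
    paste(spec$decoys, collapse = " and "))
  discussion <- sprintf(
    "Our findings position %s as a regulator of %s, with implications for disease biology.",
    mirna_raw, t1)

  sec <- function(label, text) {
    sprintf("    <sec><title>%s</title>\n      <p>%s</p>\n    </sec>",
            xml_escape(headings[[label]]), xml_escape(text))
  }
  results_sec <- sprintf(
    "    <sec><title>%s</title>\n      <p>%s</p>\n      <p>%s</p>\n    </sec>",
    xml_escape(headings[["results"]]), xml_escape(results_main),
    xml_escape(results_decoy))

  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    sprintf("<article article-type=\"%s\">\n", spec$pub_type),
    "  <front>\n    <article-meta>\n",
    sprintf("      <article-id pub-id-type=\"pmcid\">%s</article-id>\n", spec$pmcid),
    sprintf("      <article-id pub-id-type=\"pmid\">%s</article-id>\n", spec$pmid),
    sprintf("      <title-group><article-title>%s</article-title></title-group>\n",
            xml_escape(title)),
    sprintf("      <abstract><p>%s</p></abstract>\n", xml_escape(abstract)),
    "    </article-meta>\n  </front>\n",
    "  <body>\n",
    sec("introduction", intro), "\n",
    sec("methods", methods), "\n",
    results_sec, "\n",
    sec("discussion", discussion), "\n",
    "  </body>\n</article>\n")

  mention_symbols <- c(spec$targets, spec$decoys)
  mentions <- list(list(
    pmcid = spec$pmcid,
    annotations = purrr::map(mention_symbols, function(s) {
      list(exact = s, type = "Gene_Proteins")
    })
  ))
  list(xml = xml, ground_truth = synth_expected(spec), mentions = mentions,
       spec = spec)
}

normalize_composition <- function(composition) {
  p <- unlist(composition)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("composition proportions must be non-negative and sum to 1")
  }
  p
}

# exact integer apportionment by largest remainder; ties to first-listed
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    order_idx <- order(-frac, seq_along(frac))
    for (i in order_idx[seq_len(rem)]) base[[i]] <- base[[i]] + 1
  }
  as.integer(base)
}

#' Generate a random valid flowchart
#'
#' Builds a random binary decision DAG for traversal stress-testing:
#' decision nodes `d1..dn` in topological order (so the graph is acyclic by
#' construction), where each `yes` branch advances the chain (keeping every
#' node reachable) and each `no` branch independently jumps to a random
#' deeper node, a fresh terminal with a random silencing-term payload, or is
#' absent with a random `on_fail` disposition. The result always passes
#' [validate_flowchart()].
#'
#' @param n_decisions Number of decision nodes (>= 1).
#' @param seed Integer seed.
#' @return A validated `flowchart`.
#' @export
random_flowchart <- function(n_decisions, seed) {
  stopifnot(n_decisions >= 1)
  terms <- c("GO:0035195", "GO:0035278", "GO:0035279")
  with_rng(seed, {
    nodes <- list()
    n_term <- 0L
    new_terminal <- function() {
      n_term <<- n_term + 1L
      id <- paste0("t", n_term)
      nodes[[id]] <<- new_flow_node(
        id, "terminal", question = id,
        payload = list(list(term = sample(terms, 1), aspect = "BP"),
                       list(term = "GO:1903231", aspect = "MF")))
      id
    }
    for (i in seq_len(n_decisions)) {
      id <- paste0("d", i)
      yes_next <- if (i < n_decisions) paste0("d", i + 1) else new_terminal()
      u <- runif(1)
      no_next <- NULL
      on_fail <- NULL
      if (u < 0.4 && i < n_decisions) {
        # sample() treats a length-1 vector as 1:n; index the pool instead
        pool <- (i + 1):n_decisions
        no_next <- paste0("d", pool[[sample.int(length(pool), 1)]])
      } else if (u < 0.75) {
        no_next <- new_terminal()
      } else {
        on_fail <- sample(DISPOSITIONS, 1)
      }
      nodes[[id]] <- new_flow_node(
        id, "decision", question = sprintf("Q%d?", i),
        prompt = sprintf("Question %d. Answer yes or no.", i),
        section_hint = "results", yes_next = yes_next, no_next = no_next,
        on_fail = on_fail)
    }
    fc <- new_flowchart(name = sprintf("random-%d", seed), version = "1",
                        root = "d1", nodes = nodes)
    stopifnot(length(validate_flowchart(fc)) == 0)
    fc
  })
}

#' Generate a synthetic corpus with known composition
#'
#' Exact integer counts per outcome via largest-remainder apportionment
#' (ties to the first-listed outcome); per-article seeds derive from the
#' master seed, so the same `(n, composition, seed)` triple yields a
#' byte-identical corpus.
#'
#' @param n Number of articles (>= 1).
#' @param composition Named numeric vector/list of proportions summing to 1;
#'   names drawn from the outcome and exclusion classes of [synth_spec()].
#' @param seed Master seed.
#' @return A list of [generate_article()] results, in outcome-block order.
#' @export
generate_corpus <- function(n, composition, seed) {
  stopifnot(n >= 1)
  p <- normalize_composition(composition)
  counts <- apportion(n, p)
  outcomes <- rep(names(p), counts)
  purrr::imap(outcomes, function(outcome, i) {
    article_seed <- (as.integer(seed) * 7919L + as.integer(i)) %% 2147483647L
    sp <- synth_spec(outcome, seed = article_seed,
                     pmcid = sprintf("PMC%07d", 2000000L + i),
                     pmid = as.character(40000000L + i))
    generate_article(sp)
  })
}
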