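engine_fixture <- function(outcome = "term_0035279", seed = 21, ...) {
  entry <- generate_article(synth_spec(outcome, seed = seed, ...))
  list(entry = entry, article = parse_jats(entry$xml),
       mentions = parse_gene_list(entry$mentions))
}

test_that("assembled prompts combine guidance and section text, charging the budget once", {
  fx <- engine_fixture(heading_style = "canonical")
  fc <- fixture_flowchart()
  idx <- normalize_headings(fx$article, keyword_backend())
  cache <- section_cache(context_budget())
  asm1 <- assemble_prompt(fc$nodes$reporter_assay, fx$article, idx, cache)
  charged <- tokens_used(cache)
  expect_match(asm1$prompt,
               "Luciferase reporter assays where a luciferase reporter gene is fused to the 3'UTR of the target mRNA",
               fixed = TRUE)
  expect_match(asm1$prompt, asm1$section_text, fixed = TRUE)
  asm2 <- assemble_prompt(fc$nodes$mrna_level, fx$article, idx, cache)
  expect_identical(asm2$prompt == asm1$prompt, FALSE)
  expect_identical(tokens_used(cache), charged) # same section, no recharge
  expect_error(assemble_prompt(fc$nodes$t_general, fx$article, idx, cache),
               "terminal")
})

test_that("the engine recovers each flowchart outcome from its synthetic article", {
  cases <- list(
    list(outcome = "term_0035279", status = "annotated", term = "GO:0035279"),
    list(outcome = "term_0035278", status = "annotated", term = "GO:0035278"),
    list(outcome = "term_0035195", status = "annotated", term = "GO:0035195"),
    list(outcome = "filtered_no_binding", status = "filtered", term = NULL),
    list(outcome = "filtered_cluster", status = "filtered", term = NULL),
    list(outcome = "no_annotation", status = "no_annotation", term = NULL))
  for (case in cases) {
    fx <- engine_fixture(case$outcome, seed = 31)
    rec <- curate_article(fx$article, fixture_flowchart(), keyword_backend(),
                          fx$mentions, fixture_urs(), fixture_uniprot())
    expect_identical(rec$status, case$status, info = case$outcome)
    if (!is.null(case$term)) {
      expect_true(case$term %in% vapply(rec$annotations, function(a) a$go_term,
                                        character(1)),
                  info = case$outcome)
    }
    # every visited node decided exactly once, and the decisions replay
    node_ids <- vapply(rec$decisions, function(d) d$node_id, character(1))
    expect_identical(anyDuplicated(node_ids), 0L)
    expect_identical(node_ids, names(fx$entry$ground_truth$answers))
  }
})

test_that("filtered-at-triage articles stop at the triage node", {
  fx <- engine_fixture("filtered_no_binding")
  rec <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend())
  expect_identical(rec$status, "filtered")
  expect_identical(vapply(rec$decisions, function(d) d$node_id, character(1)),
                   "binding_filter")
  cl <- engine_fixture("filtered_cluster")
  rec_cl <- run_flowchart(cl$article, fixture_flowchart(), keyword_backend())
  expect_identical(rec_cl$status, "filtered")
  expect_identical(rec_cl$decisions[[2]]$node_id, "cluster_filter")
  expect_identical(rec_cl$decisions[[2]]$answer, "yes")
})

test_that("evidence spans re-validate and adversarial extractors cannot corrupt decisions", {
  fx <- engine_fixture()
  rec <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend())
  checks <- validate_record_evidence(rec)
  expect_gt(length(checks), 0)
  expect_true(all(checks))
  # decision nodes carry evidence; triage filters do not
  for (d in rec$decisions) {
    node <- fixture_flowchart()$nodes[[d$node_id]]
    if (node$kind == "filter") expect_null(d$evidence)
  }

  # adversarial span backend: answers are kept, evidence is absent with a note
  base <- record_backend(rec)
  poisoned <- base$script
  for (k in names(poisoned)) {
    if (startsWith(k, "span:")) {
      poisoned[[k]] <- list(span = "a paraphrase, not a quote",
                            start = 0L, end = 25L)
    }
  }
  bad <- scripted_backend(poisoned, name = "adversary")
  rec_bad <- run_flowchart(fx$article, fixture_flowchart(), bad)
  expect_identical(rec_bad$status, rec$status)
  expect_identical(vapply(rec_bad$decisions, function(d) d$answer, character(1)),
                   vapply(rec$decisions, function(d) d$answer, character(1)))
  for (d in rec_bad$decisions) {
    if (fixture_flowchart()$nodes[[d$node_id]]$kind == "decision") {
      expect_null(d$evidence)
      expect_match(d$span_note, "contract violation")
    }
  }
})

test_that("finalization cross-products payload and targets", {
  fx <- engine_fixture(targets = c("PTEN", "SMAD4", "TP53"), seed = 8)
  rec <- curate_article(fx$article, fixture_flowchart(), keyword_backend(),
                        fx$mentions, fixture_urs(), fixture_uniprot())
  expect_identical(rec$status, "annotated")
  expect_length(rec$annotations, 6L) # 2 payload terms x 3 targets
  pairs <- vapply(rec$annotations, function(a) paste(a$go_term, a$target_symbol),
                  character(1))
  expect_identical(anyDuplicated(pairs), 0L)
  expect_true(all(vapply(rec$annotations, function(a) !is.na(a$target_accession),
                         logical(1))))
  expect_true(all(vapply(rec$annotations, function(a) grepl("^PMID:\\d+$", a$reference),
                         logical(1))))
})

test_that("zero validated targets demotes to no_annotation with the trace preserved", {
  fx <- engine_fixture()
  rec <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend(),
                       mirna = list(normalized_id = "hsa-mir-21",
                                    urs_taxid = "URS00000001A1_9606",
                                    resolved = TRUE))
  done <- finalize_annotations(
    rec, structure(list(validated = tibble::tibble(symbol = character(),
                                                   accession = character()),
                        rejected = tibble::tibble(symbol = character(),
                                                  reason = character()),
                        unresolvable = FALSE, note = NULL, rounds = "DONE"),
                   class = "target_set"),
    fixture_flowchart())
  expect_identical(done$status, "no_annotation")
  expect_match(done$failure_note, "no validated target")
  expect_gt(length(done$decisions), 0)
})

test_that("claiming the parent term over a satisfied child path is an integrity error", {
  fx <- engine_fixture("term_0035279")
  rec <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend())
  corrupted <- rec
  corrupted$outcome <- list(
    kind = "terminal", node_id = "t_general",
    payload = list(list(term = "GO:0035195", aspect = "BP"),
                   list(term = "GO:1903231", aspect = "MF")))
  ts <- structure(list(validated = tibble::tibble(symbol = "PTEN",
                                                  accession = NA_character_),
                       rejected = tibble::tibble(symbol = character(),
                                                 reason = character()),
                       unresolvable = FALSE, note = NULL, rounds = character()),
                  class = "target_set")
  expect_error(finalize_annotations(corrupted, ts, fixture_flowchart()),
               class = "mirflow_integrity_error")
  expect_error(finalize_annotations(corrupted, ts, fixture_flowchart()),
               "less specific term")
})

test_that("a record replays byte-identically through a scripted backend", {
  for (outcome in c("term_0035278", "term_0035279", "no_annotation")) {
    fx <- engine_fixture(outcome, seed = 13)
    r1 <- curate_article(fx$article, fixture_flowchart(), keyword_backend(),
                         fx$mentions, fixture_urs(), fixture_uniprot())
    r2 <- curate_article(fx$article, fixture_flowchart(), record_backend(r1),
                         fx$mentions, fixture_urs(), fixture_uniprot())
    expect_true(records_identical(r1, r2), info = outcome)
  }
})

test_that("backend failures surface as error status, naming the failing node", {
  fx <- engine_fixture()
  partial <- scripted_backend(list(
    "heading:introduction" = "NONE", "heading:methods" = "NONE",
    "heading:results" = grep("(?i)result|finding",
                             vapply(fx$article$sections, function(s) s$heading,
                                    character(1)), value = TRUE, perl = TRUE)[[1]],
    "heading:discussion" = "NONE",
    binding_filter = "yes", cluster_filter = "no"))
  expect_error(run_flowchart(fx$article, fixture_flowchart(), partial),
               "reporter_assay")

  rogue <- keyword_backend(c(
    list(list(scope = "binding_filter", pattern = "(?i)luciferase",
              answer = "definitely")),
    default_keyword_rules()))
  rec <- run_flowchart(fx$article, fixture_flowchart(), rogue)
  expect_identical(rec$status, "error")
  expect_match(rec$failure_note, "contract violation")
})

test_that("runs never exceed the context budget, and exhaustion is an error status", {
  fx <- engine_fixture()
  rec <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend(),
                       budget = context_budget())
  expect_lte(rec$run_metadata$tokens_charged, 64000L)

  tiny <- context_budget(max_context_tokens = 3, max_evidence_source_tokens = 2)
  rec_tiny <- run_flowchart(fx$article, fixture_flowchart(), keyword_backend(),
                            budget = tiny)
  # a 3-token budget still loads a truncated first section, so the run either
  # errors on exhaustion or completes within the cap
  expect_lte(rec_tiny$run_metadata$tokens_charged %||% 0L, 3L)
})
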