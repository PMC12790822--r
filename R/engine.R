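#' The curation engine
#'
#' One run takes a pre-filtered article through the flowchart: each
#' filter/decision node is answered by a constrained yes/no choice over its
#' assembled prompt, evidence spans are captured at decision nodes, the
#' traversal follows the stored edges to a terminal payload or a
#' disposition, validated targets are attached by list-constrained
#' selection, and the result is a curation record carrying the full audit
#' trail: every prompt, answer, reasoning trace and verbatim evidence span,
#' in visit order.
#'
#' @name curation-engine
NULL

budget_abort <- function(msg) abort(msg, class = "mirflow_budget_error")

#' Assemble the prompt for one flowchart node
#'
#' The node's prepared prompt (question plus curation-manual guidance)
#' followed by the delimited text of its hinted section, loaded lazily
#' through the cache so repeated nodes on the same section charge the
#' context budget once. Deterministic for fixed inputs.
#'
#' @param node A `flow_node` (filter or decision).
#' @param article A `jats_article`.
#' @param index A `section_index`.
#' @param cache A [section_cache()].
#' @param config A [mirflow_config()].
#' @return `list(prompt, section_label, section_text, fallback)`.
#' @export
assemble_prompt <- function(node, article, index, cache,
                            config = mirflow_config()) {
  if (node$kind == "terminal") abort("terminal nodes take no prompt")
  label <- node$section_hint %||% "results"
  sec <- tryCatch(
    get_section(article, label, index, cache, config),
    error = function(e) {
      if (inherits(e, "mirflow_budget_error")) {
        budget_abort(sprintf("context budget exhausted at node '%s'", node$node_id))
      }
      stop(e)
    })
  prompt <- paste0(
    node$prompt,
    "\n\n=== ARTICLE SECTION [", label, "]",
    if (sec$fallback) " (fallback text)" else "", " ===\n",
    sec$text)
  list(prompt = prompt, section_label = label,
       section_text = sec$text, fallback = sec$fallback)
}

#' Capture an evidence span for an answered decision
#'
#' Requests a verbatim span from the node's hinted section (truncated to the
#' evidence-source cap) supporting the recorded answer. Evidence is
#' best-effort by design: a backend contract violation leaves the answer
#' intact and marks the evidence absent with the violation reason, so a
#' misbehaving extractor can never corrupt a decision.
#'
#' @param decision A decision list (with `node_id`, `answer`).
#' @param node The `flow_node` that was answered.
#' @param article A `jats_article`.
#' @param index A `section_index`.
#' @param backend A backend object.
#' @param cache A [section_cache()].
#' @param budget A [context_budget()].
#' @param config A [mirflow_config()].
#' @return The decision with an `evidence` field (list `section`, `start`,
#'   `end`, `span`, `reasoning`) or `span_note` on failure.
#' @export
attach_evidence <- function(decision, node, article, index, backend, cache,
                            budget = context_budget(),
                            config = mirflow_config()) {
  label <- node$section_hint %||% "results"
  sec_text <- get_section(article, label, index, cache, config)$text
  req <- span_request(
    key = paste0("span:", node$node_id),
    prompt = paste0(
      "Quote the passage from the section below that best supports the ",
      "answer '", decision$answer, "' to: ", node$question),
    source = sec_text,
    max_source_tokens = budget$max_evidence_source_tokens
  )
  resp <- tryCatch(extract_span(backend, req), mirflow_contract_violation = identity)
  if (inherits(resp, "condition")) {
    decision$evidence <- NULL
    decision$span_note <- paste0("evidence rejected: ", conditionMessage(resp))
  } else {
    decision$evidence <- list(
      section = label, start = resp$start, end = resp$end,
      span = resp$span, reasoning = resp$reasoning)
    decision$evidence_source <- req$source
  }
  decision
}

#' Run the flowchart over one article
#'
#' Traverses from the root: every filter/decision node visited yields
#' exactly one decision entry (prompt, constrained yes/no answer, reasoning
#' trace, and — at decision nodes — an evidence span). Dispositions map to
#' status `filtered`/`no_annotation`; reaching a terminal leaves the record
#' in status `annotated` pending target attachment
#' ([finalize_annotations()]). Backend contract violations and context
#' budget exhaustion produce status `error` with the failure recorded, never
#' a partial silent result.
#'
#' @param article A `jats_article` that passed the corpus filter.
#' @param fc A validated `flowchart`.
#' @param backend A backend object.
#' @param budget A [context_budget()].
#' @param config A [mirflow_config()].
#' @param mirna Optional mention info (list with `normalized_id`,
#'   `urs_taxid`, `resolved`) recorded on the record.
#' @return A `curation_record`.
#' @export
run_flowchart <- function(article, fc, backend,
                          budget = context_budget(),
                          config = mirflow_config(),
                          mirna = NULL) {
  cache <- section_cache(budget)
  record <- structure(
    list(
      pmcid = article$pmcid, pmid = article$pmid,
      mirna = mirna,
      decisions = list(),
      status = NA_character_,
      outcome = NULL,
      annotations = list(),
      failure_note = NULL,
      heading_choices = list(),
      sections = list(),
      target_rounds = character(),
      run_metadata = list(
        flowchart_name = fc$name, flowchart_version = fc$version,
        backend = backend$name, config_hash = config_hash(config),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    ),
    class = "curation_record"
  )

  result <- tryCatch({
    index <- normalize_headings(article, backend)
    record$heading_choices <- heading_choices_of(index, article)
    current <- fc$root
    repeat {
      node <- fc$nodes[[current]]
      if (node$kind == "terminal") {
        record$outcome <- outcome_terminal(node)
        record$status <- "annotated"
        break
      }
      asm <- assemble_prompt(node, article, index, cache, config)
      req <- choice_request(key = node$node_id, prompt = asm$prompt,
                            options = c("yes", "no"),
                            context = asm$section_text)
      resp <- choose(backend, req)
      decision <- list(
        node_id = node$node_id, answer = resp$selected,
        reasoning = resp$reasoning,
        reasoning_tokens_used = resp$reasoning_tokens_used,
        prompt_used = asm$prompt)
      if (node$kind == "decision") {
        decision <- attach_evidence(decision, node, article, index, backend,
                                    cache, budget, config)
        if (!is.null(decision$evidence)) {
          record$sections[[decision$evidence$section]] <- decision$evidence_source
          decision$evidence_source <- NULL
        }
      }
      record$decisions[[length(record$decisions) + 1]] <- decision
      res <- flow_step(fc, current, resp$selected)
      if (res$kind == "disposition") {
        record$outcome <- res
        record$status <- res$value
        break
      }
      if (res$kind == "terminal") {
        record$outcome <- res
        record$status <- "annotated"
        break
      }
      current <- res$node_id
    }
    record$run_metadata$tokens_charged <- tokens_used(cache)
    record$run_metadata$load_log <- cache$log
    record
  },
  mirflow_contract_violation = function(e) {
    record$status <- "error"
    record$failure_note <- conditionMessage(e)
    record
  },
  mirflow_budget_error = function(e) {
    record$status <- "error"
    record$failure_note <- conditionMessage(e)
    record
  })
  result
}

heading_choices_of <- function(index, article) {
  out <- list()
  for (label in setdiff(CANONICAL_LABELS, "abstract")) {
    out[[paste0("heading:", label)]] <- index[[label]] %||% "NONE"
  }
  out
}

index_from_choices <- function(choices, article) {
  index <- list()
  if (nzchar(article$abstract)) index[["abstract"]] <- "[abstract]"
  for (key in names(choices)) {
    label <- sub("^heading:", "", key)
    if (!identical(choices[[key]], "NONE")) index[[label]] <- choices[[key]]
  }
  structure(index, class = "section_index")
}

answers_of <- function(record) {
  ans <- vapply(record$decisions, function(d) d$answer, character(1))
  setNames(ans, vapply(record$decisions, function(d) d$node_id, character(1)))
}

#' Finalize a record into annotations
#'
#' Cross-products the terminal payload with the validated targets into one
#' annotation per (GO term, target) pair, anchored on the miRNA's URS_taxid.
#' Before emitting, an integrity check replays the recorded answer vector
#' through the flowchart and requires it to reach the recorded terminal —
#' in particular, a record claiming only the parent silencing term while its
#' answers satisfy a mechanism-specific child path is an integrity error,
#' never a silent under-annotation. Zero validated targets (or an
#' unresolvable set) demotes the record to `no_annotation` with an explicit
#' note: these annotations are target-anchored triples, and the trace is
#' preserved for review.
#'
#' @param record A `curation_record` whose outcome is a terminal payload.
#' @param targets A `target_set` (accessions already mapped).
#' @param fc The `flowchart` the record was produced with.
#' @param config A [mirflow_config()].
#' @return The finalized `curation_record`.
#' @export
finalize_annotations <- function(record, targets, fc,
                                 config = mirflow_config()) {
  if (is.null(record$outcome) || record$outcome$kind != "terminal") {
    abort("finalize_annotations: record outcome is not a terminal payload")
  }
  replayed <- replay_answers(fc, answers_of(record))
  if (replayed$kind != "terminal" ||
      !identical(replayed$node_id, record$outcome$node_id)) {
    claimed <- payload_terms(record$outcome$payload)
    reached <- if (replayed$kind == "terminal") {
      payload_terms(replayed$payload)
    } else {
      replayed$value
    }
    # claiming the parent term while the answers satisfy a child-term path
    # is the specificity failure this check exists for
    reached_children <- intersect(reached, names(fc$term_hierarchy))
    parents_of_reached <- unlist(fc$term_hierarchy[reached_children], use.names = FALSE)
    specificity <- length(reached_children) > 0 && any(parents_of_reached %in% claimed)
    abort(sprintf(
      "record integrity error: decisions replay to %s but outcome claims %s%s",
      paste(reached, collapse = "+"), paste(claimed, collapse = "+"),
      if (specificity) " (less specific term claimed where a child path is satisfied)" else ""),
      class = "mirflow_integrity_error")
  }
  if (length(targets$rounds) > 0) record$target_rounds <- targets$rounds
  if (targets$unresolvable || nrow(targets$validated) == 0) {
    record$status <- "no_annotation"
    record$failure_note <- targets$note %||% "no validated target"
    record$annotations <- list()
    return(record)
  }
  subject <- record$mirna$urs_taxid %||% NA_character_
  anns <- list()
  for (i in seq_len(nrow(targets$validated))) {
    sym <- targets$validated$symbol[[i]]
    acc <- targets$validated$accession[[i]]
    for (p in record$outcome$payload) {
      anns[[length(anns) + 1]] <- list(
        subject_urs_taxid = subject,
        go_term = p$term,
        aspect = p$aspect,
        relation = if (p$aspect == "BP") config$relation_bp else config$relation_mf,
        target_symbol = sym,
        target_accession = acc,
        reference = if (is.null(record$pmid)) NA_character_ else paste0("PMID:", record$pmid),
        evidence_code = config$evidence_code,
        assigned_by = config$assigned_by)
    }
  }
  record$annotations <- anns
  record$status <- "annotated"
  record
}

payload_terms <- function(payload) {
  vapply(payload, function(p) p$term, character(1))
}

#' Curate one article end to end
#'
#' The full per-article pipeline: corpus screening, URS resolution of the
#' single miRNA, flowchart traversal, target selection constrained to the
#' gene mention list, UniProtKB mapping, and annotation assembly. Articles
#' failing the corpus screen come back as status `filtered` with the filter
#' reasons in the failure note and no flowchart run.
#'
#' @param article A `jats_article`.
#' @param fc A validated `flowchart`.
#' @param backend A backend object.
#' @param mentions A `gene_mention_list` (or `NULL` to skip target
#'   resolution, leaving a terminal record with no targets).
#' @param urs_lookup Named vector from [load_urs_lookup()] (or `NULL`).
#' @param uniprot_lookup Table from [load_uniprot_lookup()] (or `NULL`).
#' @param budget A [context_budget()].
#' @param config A [mirflow_config()].
#' @return A finalized `curation_record`.
#' @export
curate_article <- function(article, fc, backend, mentions = NULL,
                           urs_lookup = NULL, uniprot_lookup = NULL,
                           budget = context_budget(),
                           config = mirflow_config()) {
  report <- filter_article(article)
  if (!report$passed) {
    return(structure(
      list(pmcid = article$pmcid, pmid = article$pmid, mirna = NULL,
           decisions = list(), status = "filtered", outcome = NULL,
           annotations = list(),
           failure_note = paste0("corpus filter: ",
                                 paste(report$reasons[[1]], collapse = ", ")),
           heading_choices = list(), sections = list(),
           target_rounds = character(),
           run_metadata = list(
             flowchart_name = fc$name, flowchart_version = fc$version,
             backend = backend$name, config_hash = config_hash(config),
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
      class = "curation_record"))
  }
  mirna <- list(normalized_id = report$mirna_id, urs_taxid = NULL, resolved = FALSE)
  if (!is.null(urs_lookup) && report$mirna_id %in% names(urs_lookup)) {
    mirna$urs_taxid <- unname(urs_lookup[[report$mirna_id]])
    mirna$resolved <- TRUE
  }
  record <- run_flowchart(article, fc, backend, budget, config, mirna = mirna)
  if (record$status != "annotated") return(record)

  cache <- section_cache(budget)
  index <- index_from_choices(record$heading_choices, article)
  targets <- if (is.null(mentions)) {
    new_target_set(character(),
                   tibble(symbol = character(), reason = character()),
                   unresolvable = TRUE, note = "no gene mention list supplied")
  } else {
    tryCatch(
      select_targets(article, mentions, backend, index, cache, config),
      mirflow_contract_violation = function(e) {
        record$status <<- "error"
        record$failure_note <<- conditionMessage(e)
        NULL
      })
  }
  if (is.null(targets)) return(record)
  if (!is.null(uniprot_lookup) && nrow(targets$validated) > 0 &&
      !is.null(mirna$urs_taxid)) {
    taxon <- sub("^.*_", "", mirna$urs_taxid)
    targets$validated$accession <- vapply(
      targets$validated$symbol, map_to_uniprot, character(1),
      lookup = uniprot_lookup, taxon = taxon)
  }
  finalize_annotations(record, targets, fc, config)
}

#' Rebuild a scripted backend from a record's own trace
#'
#' Every answer, evidence span, heading choice and target pick stored in a
#' record becomes a script entry, so feeding the result to
#' [curate_article()] replays the run deterministically. The backend keeps
#' the original backend's name so the replayed record is identical modulo
#' timestamp.
#'
#' @param record A `curation_record`.
#' @return A [scripted_backend()].
#' @export
record_backend <- function(record) {
  script <- list()
  for (key in names(record$heading_choices)) {
    script[[key]] <- record$heading_choices[[key]]
  }
  for (d in record$decisions) {
    script[[d$node_id]] <- list(selected = d$answer, reasoning = d$reasoning,
                                reasoning_tokens_used = d$reasoning_tokens_used)
    if (!is.null(d$evidence)) {
      script[[paste0("span:", d$node_id)]] <- list(
        start = d$evidence$start, end = d$evidence$end,
        reasoning = d$evidence$reasoning)
    }
  }
  for (i in seq_along(record$target_rounds)) {
    script[[paste0("target:", i)]] <- record$target_rounds[[i]]
  }
  scripted_backend(script, name = record$run_metadata$backend)
}

#' Re-validate every stored evidence span in a record
#'
#' Checks `substr(section_text, start + 1, end) == span` (0-based half-open
#' offsets) for each decision that carries evidence, against the section
#' text stored with the record.
#'
#' @param record A `curation_record`.
#' @return Logical vector, one entry per evidence span.
#' @export
validate_record_evidence <- function(record) {
  out <- logical()
  for (d in record$decisions) {
    ev <- d$evidence
    if (is.null(ev)) next
    src <- record$sections[[ev$section]]
    out <- c(out, !is.null(src) &&
               identical(substr(src, ev$start + 1, ev$end), ev$span))
  }
  out
}

#' @export
print.curation_record <- function(x, ...) {
  cat(sprintf("<curation_record> %s [%s] %d decision(s), %d annotation(s)\n",
              x$pmcid %||% "?", x$status, length(x$decisions),
              length(x$annotations)))
  invisible(x)
}

#' Decisions of a record as a tibble
#' @param x A `curation_record`.
#' @param ... Unused.
#' @return A tibble with one row per visited node.
#' @export
tidy.curation_record <- function(x, ...) {
  purrr::map_dfr(x$decisions, function(d) {
    tibble(node_id = d$node_id, answer = d$answer,
           reasoning_tokens = d$reasoning_tokens_used %||% NA_integer_,
           has_evidence = !is.null(d$evidence),
           evidence_span = if (is.null(d$evidence)) NA_character_ else d$evidence$span)
  })
}

#' One-row summary of a record
#' @param x A `curation_record`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.curation_record <- function(x, ...) {
  tibble(
    pmcid = x$pmcid %||% NA_character_,
    status = x$status,
    n_decisions = length(x$decisions),
    n_annotations = length(x$annotations),
    go_terms = paste(unique(vapply(x$annotations, function(a) a$go_term,
                                   character(1))), collapse = ";"),
    targets = paste(unique(vapply(x$annotations, function(a) a$target_symbol,
                                  character(1))), collapse = ";"))
}
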