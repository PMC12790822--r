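#' Curation flowcharts
#'
#' A flowchart is a typed DAG of `filter`, `decision` and `terminal` nodes.
#' Filter and decision nodes carry a yes/no question (and the long prompt sent
#' to the backend); each of their two branches either names a successor node
#' or falls through to an `on_fail` disposition (`"filtered"` for triage
#' filters, `"no_annotation"` for decision dead-ends). Terminal nodes carry a
#' payload of (GO term, aspect) pairs to annotate. An `is_a` child-to-parent
#' map over the payload terms records the local ontology hierarchy, used by
#' the engine's specificity check.
#'
#' The on-disk form is two JSON files: the flowchart proper and a companion
#' file mapping every node id to its prompt text. A JSON-Schema document
#' describing the flowchart file ships at
#' `system.file("extdata", "flowchart.schema.json", package = "mirflow")`;
#' validation itself is performed by [validate_flowchart()].
#'
#' @name flowchart
NULL

GO_ID_RX <- "^GO:\\d{7}$"
DISPOSITIONS <- c("filtered", "no_annotation")

new_flow_node <- function(node_id, kind, question = "", prompt = "",
                          section_hint = NULL, yes_next = NULL, no_next = NULL,
                          on_fail = NULL, payload = NULL) {
  structure(
    list(node_id = node_id, kind = kind, question = question, prompt = prompt,
         section_hint = section_hint, yes_next = yes_next, no_next = no_next,
         on_fail = on_fail, payload = payload),
    class = "flow_node"
  )
}

new_flowchart <- function(name, version, root, nodes, term_hierarchy = list()) {
  structure(
    list(name = name, version = version, root = root, nodes = nodes,
         term_hierarchy = term_hierarchy),
    class = "flowchart"
  )
}

#' @export
print.flowchart <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<flowchart> %s v%s: %d nodes (%d filter, %d decision, %d terminal), root '%s'\n",
              x$name, x$version, length(x$nodes),
              sum(kinds == "filter"), sum(kinds == "decision"),
              sum(kinds == "terminal"), x$root))
  invisible(x)
}

#' Load a flowchart and its prompts from JSON
#'
#' Reads the flowchart JSON and the companion prompts JSON (a flat mapping
#' `node_id -> prompt string`), attaches the prompt text to each node, and
#' validates the result. Loading fails if any node lacks a prompt entry or if
#' structural validation reports violations.
#'
#' @param flowchart_json Path to the flowchart JSON file.
#' @param prompts_json Path to the prompts JSON file.
#' @return A validated `flowchart` object.
#' @seealso [mirna_flowchart()] for the bundled miRNA gene-silencing fixture.
#' @export
load_flowchart <- function(flowchart_json, prompts_json) {
  fc_raw <- jsonlite::read_json(flowchart_json)
  prompts <- jsonlite::read_json(prompts_json)
  for (field in c("name", "version", "root", "nodes")) {
    if (is.null(fc_raw[[field]])) {
      abort(sprintf("flowchart schema violation at /%s: missing required field", field))
    }
  }
  nodes <- list()
  for (id in names(fc_raw$nodes)) {
    raw <- fc_raw$nodes[[id]]
    if (is.null(raw$kind) || !raw$kind %in% c("filter", "decision", "terminal")) {
      abort(sprintf("flowchart schema violation at /nodes/%s/kind: must be filter|decision|terminal", id))
    }
    payload <- NULL
    if (!is.null(raw$payload)) {
      payload <- purrr::map(raw$payload, function(p) {
        if (is.null(p$term) || is.null(p$aspect)) {
          abort(sprintf("flowchart schema violation at /nodes/%s/payload: entries need term and aspect", id))
        }
        list(term = p$term, aspect = p$aspect)
      })
    }
    if (is.null(prompts[[id]])) {
      abort(sprintf("missing prompt for node '%s' in %s", id, prompts_json))
    }
    nodes[[id]] <- new_flow_node(
      node_id = id, kind = raw$kind,
      question = raw$question %||% "",
      prompt = prompts[[id]],
      section_hint = raw$section_hint,
      yes_next = raw$yes_next, no_next = raw$no_next,
      on_fail = raw$on_fail, payload = payload
    )
  }
  fc <- new_flowchart(
    name = fc_raw$name, version = fc_raw$version, root = fc_raw$root,
    nodes = nodes,
    term_hierarchy = lapply(fc_raw$term_hierarchy %||% list(), as.character)
  )
  violations <- validate_flowchart(fc)
  if (length(violations) > 0) {
    abort(paste0("invalid flowchart:\n", paste("-", violations, collapse = "\n")))
  }
  fc
}

#' Validate a flowchart's structural invariants
#'
#' Checks, without raising, every structural rule a flowchart must satisfy:
#' the root exists; branch edges reference defined nodes; filter/decision
#' nodes have both branches covered (by an edge or an `on_fail` disposition);
#' terminals have a non-empty payload and no out-edges; GO ids match
#' `GO:\\d{7}`; all nodes are reachable from the root; the graph is acyclic;
#' at least one terminal is reachable; and `term_hierarchy` only mentions
#' payload terms.
#'
#' @param fc A `flowchart` object.
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_flowchart <- function(fc) {
  v <- character()
  ids <- names(fc$nodes)
  if (!fc$root %in% ids) {
    v <- c(v, sprintf("root '%s' is not a defined node", fc$root))
    return(v)
  }
  for (n in fc$nodes) {
    for (edge in c("yes_next", "no_next")) {
      nxt <- n[[edge]]
      if (!is.null(nxt) && !nxt %in% ids) {
        v <- c(v, sprintf("node '%s': dangling edge %s -> '%s'", n$node_id, edge, nxt))
      }
    }
    if (n$kind %in% c("filter", "decision")) {
      missing_branches <- sum(is.null(n$yes_next), is.null(n$no_next))
      if (missing_branches > 0 && is.null(n$on_fail)) {
        v <- c(v, sprintf("node '%s': %d branch(es) missing and no on_fail disposition",
                          n$node_id, missing_branches))
      }
      if (missing_branches == 0 && !is.null(n$on_fail)) {
        v <- c(v, sprintf("node '%s': on_fail set but both branches populated", n$node_id))
      }
      if (!is.null(n$on_fail) && !n$on_fail %in% DISPOSITIONS) {
        v <- c(v, sprintf("node '%s': on_fail '%s' is not a known disposition",
                          n$node_id, n$on_fail))
      }
      if (!is.null(n$payload)) {
        v <- c(v, sprintf("node '%s': non-terminal carries a payload", n$node_id))
      }
    } else {
      if (!is.null(n$yes_next) || !is.null(n$no_next)) {
        v <- c(v, sprintf("node '%s': terminal has out-edge", n$node_id))
      }
      if (length(n$payload) == 0) {
        v <- c(v, sprintf("node '%s': terminal has empty payload", n$node_id))
      }
      for (p in n$payload) {
        if (!grepl(GO_ID_RX, p$term)) {
          v <- c(v, sprintf("node '%s': payload term '%s' does not match GO:NNNNNNN",
                            n$node_id, p$term))
        }
        if (!p$aspect %in% c("BP", "MF")) {
          v <- c(v, sprintf("node '%s': payload aspect '%s' not BP/MF", n$node_id, p$aspect))
        }
      }
    }
  }
  # reachability + cycle detection (iterative DFS with colouring)
  colour <- setNames(rep("white", length(ids)), ids)
  cyclic <- FALSE
  visit <- function(id) {
    stack <- list(list(id = id, phase = "enter"))
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (top$phase == "enter") {
        if (colour[[top$id]] == "grey") next
        if (colour[[top$id]] == "black") next
        colour[[top$id]] <<- "grey"
        stack[[length(stack) + 1]] <- list(id = top$id, phase = "exit")
        n <- fc$nodes[[top$id]]
        for (nxt in c(n$yes_next, n$no_next)) {
          if (!is.null(nxt) && nxt %in% ids) {
            if (colour[[nxt]] == "grey") cyclic <<- TRUE
            if (colour[[nxt]] == "white") {
              stack[[length(stack) + 1]] <- list(id = nxt, phase = "enter")
            }
          }
        }
      } else {
        colour[[top$id]] <<- "black"
      }
    }
  }
  visit(fc$root)
  if (cyclic) v <- c(v, "directed cycle reachable from root")
  unreachable <- ids[colour[ids] == "white"]
  for (id in unreachable) {
    v <- c(v, sprintf("node '%s': unreachable from root (prompt never used)", id))
  }
  reachable <- ids[colour[ids] != "white"]
  term_reached <- any(vapply(reachable, function(id) fc$nodes[[id]]$kind == "terminal", logical(1)))
  if (!term_reached) v <- c(v, "no terminal reachable from root")
  payload_terms <- unique(unlist(lapply(fc$nodes, function(n) {
    vapply(n$payload %||% list(), function(p) p$term, character(1))
  })))
  hier_terms <- unique(c(names(fc$term_hierarchy), unlist(fc$term_hierarchy)))
  parents <- unique(unlist(fc$term_hierarchy))
  for (t in setdiff(hier_terms, c(payload_terms, parents))) {
    v <- c(v, sprintf("term_hierarchy mentions '%s', absent from all terminal payloads", t))
  }
  v
}

outcome_terminal <- function(node) {
  list(kind = "terminal", node_id = node$node_id, payload = node$payload)
}
outcome_disposition <- function(disp) {
  list(kind = "disposition", value = disp)
}

#' Advance one step through a flowchart
#'
#' Deterministic successor lookup: given a filter/decision node and a yes/no
#' answer, returns the next node id, or — when the branch is absent — the
#' node's `on_fail` disposition, or the terminal payload when the successor is
#' a terminal. The three cases are distinguished by the `kind` field of the
#' returned list (`"node"`, `"disposition"`, `"terminal"`).
#'
#' @param fc A validated `flowchart`.
#' @param node_id Id of a filter or decision node.
#' @param answer `"yes"` or `"no"`.
#' @return A list with `kind` and, per case, `node_id`/`payload`/`value`.
#' @export
flow_step <- function(fc, node_id, answer) {
  node <- fc$nodes[[node_id]]
  if (is.null(node)) abort(sprintf("unknown node '%s'", node_id))
  if (node$kind == "terminal") abort(sprintf("cannot step from terminal node '%s'", node_id))
  answer <- match.arg(answer, c("yes", "no"))
  nxt <- if (answer == "yes") node$yes_next else node$no_next
  if (is.null(nxt)) {
    return(outcome_disposition(node$on_fail))
  }
  succ <- fc$nodes[[nxt]]
  if (succ$kind == "terminal") outcome_terminal(succ) else list(kind = "node", node_id = nxt)
}

#' Enumerate every root-to-outcome path
#'
#' Exhaustively unrolls the decision tree: each entry pairs an answer vector
#' (the ordered yes/no answers at every filter/decision node on one path)
#' with its outcome (a terminal payload or a disposition). Used both as the
#' traversal oracle in tests and to pre-compute ground-truth paths for the
#' synthetic corpus.
#'
#' @param fc A validated `flowchart`.
#' @return A list of `list(answers = named chr, outcome = list)` entries.
#' @export
enumerate_paths <- function(fc) {
  paths <- list()
  recurse <- function(node_id, answers, seen) {
    if (node_id %in% seen) abort(sprintf("cycle detected at node '%s'", node_id))
    node <- fc$nodes[[node_id]]
    if (node$kind == "terminal") {
      paths[[length(paths) + 1]] <<- list(answers = answers, outcome = outcome_terminal(node))
      return(invisible(NULL))
    }
    for (ans in c("yes", "no")) {
      nxt <- if (ans == "yes") node$yes_next else node$no_next
      a2 <- c(answers, setNames(ans, node_id))
      if (is.null(nxt)) {
        paths[[length(paths) + 1]] <<- list(answers = a2,
                                            outcome = outcome_disposition(node$on_fail))
      } else {
        recurse(nxt, a2, c(seen, node_id))
      }
    }
  }
  root <- fc$nodes[[fc$root]]
  if (root$kind == "terminal") {
    return(list(list(answers = setNames(character(0), character(0)),
                     outcome = outcome_terminal(root))))
  }
  recurse(fc$root, setNames(character(0), character(0)), character(0))
  paths
}

#' Replay a complete answer vector through a flowchart
#'
#' Iterates [flow_step()] from the root, consuming the answer recorded for
#' each visited node, until a terminal or disposition is reached.
#'
#' @param fc A validated `flowchart`.
#' @param answers Named character vector, `node_id -> "yes"/"no"`.
#' @return The outcome list, as produced by [flow_step()].
#' @export
replay_answers <- function(fc, answers) {
  node <- fc$nodes[[fc$root]]
  if (node$kind == "terminal") return(outcome_terminal(node))
  current <- fc$root
  repeat {
    if (!current %in% names(answers)) {
      abort(sprintf("answer vector does not cover visited node '%s'", current))
    }
    res <- flow_step(fc, current, answers[[current]])
    if (res$kind != "node") return(res)
    current <- res$node_id
  }
}

#' The bundled miRNA gene-silencing flowchart
#'
#' Loads the packaged curation flowchart for miRNA-mediated post-transcriptional
#' gene silencing. The fixture is a reconstruction of the GO consortium's
#' miRNA annotation guidance from its published description (the original
#' wiki figure is an image): two pre-flowchart triage filters (binding
#' experiments mentioned; miRNA-cluster study), a reporter-assay gate, and
#' two mechanism decisions separating mRNA destabilization (GO:0035279) from
#' translational inhibition (GO:0035278), with the parent term GO:0035195 as
#' the mechanism-unresolved outcome. Every terminal also carries the MF
#' co-term GO:1903231 (mRNA base-pairing post-transcriptional repressor
#' activity).
#'
#' @return A validated `flowchart`.
#' @export
#' @examples
#' fc <- mirna_flowchart()
#' length(enumerate_paths(fc))
mirna_flowchart <- function() {
  load_flowchart(
    system.file("extdata", "mirna_flowchart.json", package = "mirflow"),
    system.file("extdata", "mirna_prompts.json", package = "mirflow")
  )
}

#' Flowchart nodes as a tibble
#'
#' @param x A `flowchart`.
#' @param ... Unused.
#' @return A tibble with one row per node.
#' @export
tidy.flowchart <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(n) {
    tibble(
      node_id = n$node_id, kind = n$kind, question = n$question,
      section_hint = n$section_hint %||% NA_character_,
      yes_next = n$yes_next %||% NA_character_,
      no_next = n$no_next %||% NA_character_,
      on_fail = n$on_fail %||% NA_character_,
      terms = paste(vapply(n$payload %||% list(), function(p) p$term, character(1)),
                    collapse = ";")
    )
  })
}
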