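#' Target-gene resolution
#'
#' Verbatim substring extraction does not reliably end at gene-name
#' boundaries, so target genes are resolved against the gene/protein mention
#' list that the EuropePMC annotations API publishes for every open-access
#' article. The backend is then asked to *select* validated targets from
#' that closed list by constrained choice — it can never invent a symbol.
#' Two sentinels extend the option list: `DONE` ends the selection loop, and
#' `NOT_IN_LIST` lets the backend signal that the true target is missing
#' from the mention list (a known failure mode of list-constrained
#' selection) instead of being forced onto a wrong symbol.
#'
#' @name target-resolution
NULL

#' Parse a EuropePMC annotations payload into a gene mention list
#'
#' Accepts the JSON shape of the
#' `annotationsByArticleIds?...&type=Gene_Proteins` endpoint: an array of
#' article objects, each with an `annotations` array whose entries carry the
#' matched surface string in `exact`. Symbols are de-duplicated preserving
#' first-appearance order.
#'
#' @param payload Parsed JSON (list), a JSON string, or a path to a JSON
#'   file.
#' @param pmcid Optional: restrict to the entry for this PMC id.
#' @return A `gene_mention_list`: list with `pmcid`, `symbols`, `source`.
#' @export
parse_gene_list <- function(payload, pmcid = NULL) {
  if (is.character(payload)) {
    payload <- if (length(payload) == 1 && file.exists(payload)) {
      jsonlite::read_json(payload)
    } else {
      jsonlite::fromJSON(paste(payload, collapse = "\n"), simplifyVector = FALSE)
    }
  }
  if (!is.null(payload$articles)) payload <- payload$articles
  if (!is.null(payload$annotations)) payload <- list(payload)
  entry <- NULL
  for (art in payload) {
    art_id <- art$pmcid %||% sub("^PMC:", "PMC", art$extId %||% "")
    if (is.null(pmcid) || identical(art_id, pmcid)) {
      entry <- art
      if (is.null(entry$pmcid)) entry$pmcid <- art_id
      break
    }
  }
  if (is.null(entry)) {
    abort(sprintf("no annotations entry found%s",
                  if (is.null(pmcid)) "" else paste0(" for ", pmcid)))
  }
  if (is.null(entry$annotations)) {
    abort(sprintf("malformed annotations payload at articles/%s: missing 'annotations' field",
                  entry$pmcid %||% "?"))
  }
  symbols <- vapply(entry$annotations, function(a) {
    if (is.null(a$exact)) abort("malformed annotation entry: missing 'exact'")
    a$exact
  }, character(1))
  structure(
    list(pmcid = entry$pmcid, symbols = unique(symbols), source = "fixture"),
    class = "gene_mention_list"
  )
}

#' Fetch the gene mention list for an article
#'
#' With a fixture client (a path to a saved payload, or a parsed payload),
#' reads offline; with `client = "live"` queries the EuropePMC annotations
#' API over HTTP (opt-in; never used in tests).
#'
#' @param pmcid PMC identifier, `PMC\\d+`.
#' @param client Path/payload for fixture mode, or `"live"`.
#' @return A `gene_mention_list`.
#' @export
fetch_gene_list <- function(pmcid, client) {
  if (!grepl("^PMC\\d+$", pmcid)) abort(sprintf("malformed pmcid '%s'", pmcid))
  if (identical(client, "live")) {
    url <- paste0(
      "https://www.ebi.ac.uk/europepmc/annotations_api/annotationsByArticleIds",
      "?articleIds=PMC%3A", sub("^PMC", "", pmcid),
      "&type=Gene_Proteins&provider=Europe%20PMC&format=JSON")
    payload <- tryCatch(jsonlite::read_json(url), error = function(e) {
      abort(paste0("annotations API request failed (retryable): ",
                   conditionMessage(e)))
    })
    out <- parse_gene_list(payload, pmcid = pmcid)
    out$source <- "live_api"
    return(out)
  }
  parse_gene_list(client, pmcid = pmcid)
}

#' Select validated targets from the mention list
#'
#' Runs the constrained selection loop: at round *n* the backend is offered
#' the not-yet-chosen symbols plus `DONE` and `NOT_IN_LIST` under routing
#' key `target:<n>`, with the article's hinted evidence section as context.
#' `DONE` ends the loop; `NOT_IN_LIST` marks the set unresolvable; at most
#' `config$max_targets` symbols are kept (further picks are rejected with
#' reason `"limit"`).
#'
#' @param article A `jats_article`.
#' @param mentions A `gene_mention_list`.
#' @param backend A backend object.
#' @param index A `section_index`.
#' @param cache A [section_cache()].
#' @param config A [mirflow_config()].
#' @return A `target_set`: list with `validated` (tibble `symbol`,
#'   `accession`), `rejected` (tibble `symbol`, `reason`), `unresolvable`,
#'   `note`.
#' @export
select_targets <- function(article, mentions, backend, index, cache,
                           config = mirflow_config()) {
  if (length(mentions$symbols) == 0) {
    return(new_target_set(character(), tibble(symbol = character(), reason = character()),
                          unresolvable = TRUE,
                          note = "empty gene mention list"))
  }
  rounds <- character()
  context <- get_section(article, "results", index, cache, config)$text
  chosen <- character()
  rejected <- tibble(symbol = character(), reason = character())
  unresolvable <- FALSE
  note <- NULL
  round <- 0L
  repeat {
    round <- round + 1L
    remaining <- setdiff(mentions$symbols, chosen)
    if (length(remaining) == 0 || round > length(mentions$symbols) + 1L) break
    req <- choice_request(
      key = paste0("target:", round),
      prompt = paste0(
        "Which gene from the list is validated as a direct target of the ",
        "miRNA in this article (one at a time)? Answer DONE when all ",
        "validated targets have been named, or NOT_IN_LIST if the true ",
        "target is absent from the list.\nList: ",
        paste(remaining, collapse = ", "), "\n\n", context),
      options = c(remaining, "DONE", "NOT_IN_LIST"),
      context = context
    )
    resp <- choose(backend, req)
    rounds <- c(rounds, resp$selected)
    if (resp$selected == "DONE") break
    if (resp$selected == "NOT_IN_LIST") {
      unresolvable <- TRUE
      note <- "backend signalled the validated target is absent from the mention list"
      chosen <- character()
      break
    }
    if (length(chosen) >= config$max_targets) {
      rejected <- dplyr::bind_rows(rejected,
                                   tibble(symbol = resp$selected, reason = "limit"))
    } else {
      chosen <- c(chosen, resp$selected)
    }
  }
  new_target_set(chosen, rejected, unresolvable, note, rounds = rounds)
}

new_target_set <- function(validated, rejected, unresolvable, note = NULL,
                           rounds = character()) {
  structure(
    list(validated = tibble(symbol = validated,
                            accession = rep(NA_character_, length(validated))),
         rejected = rejected, unresolvable = unresolvable, note = note,
         rounds = rounds),
    class = "target_set"
  )
}

#' Load a gene-symbol-to-UniProtKB lookup table
#'
#' Tab-separated with header `symbol`, `taxon`, `accession`; duplicate
#' `(symbol, taxon)` keys are a load-time error.
#'
#' @param path Path to the TSV.
#' @return A data frame keyed by symbol and taxon.
#' @export
load_uniprot_lookup <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(taxon = "character"))
  if (!all(c("symbol", "taxon", "accession") %in% names(tab))) {
    abort("UniProt lookup must have columns symbol, taxon, accession")
  }
  key <- paste(tab$symbol, tab$taxon)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate (symbol, taxon) key(s) in UniProt lookup: %s",
                  paste(unique(dup), collapse = "; ")))
  }
  tab
}

#' Map a gene symbol to a UniProtKB accession
#'
#' Exact `(symbol, taxon)` match; a miss returns `NA` (the annotation is
#' still emitted, carrying the bare symbol, and flagged downstream).
#'
#' @param symbol Gene symbol as it appears in the mention list.
#' @param lookup Table from [load_uniprot_lookup()].
#' @param taxon NCBI taxon id (character or integer), typically derived
#'   from the miRNA's URS_taxid suffix.
#' @return Accession string or `NA_character_`.
#' @export
map_to_uniprot <- function(symbol, lookup, taxon) {
  hit <- lookup$accession[lookup$symbol == symbol & lookup$taxon == as.character(taxon)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}
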