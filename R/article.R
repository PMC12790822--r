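#' Token counting
#'
#' Deterministic, model-free token counter used for all context budgeting:
#' the number of whitespace-delimited words. Monotone under concatenation and
#' within one token of additive. Model-specific tokenizers can be substituted
#' wherever a `counter` argument is accepted, but the default keeps tests and
#' budgets reproducible without any model.
#'
#' @param text Character scalar.
#' @return Non-negative integer.
#' @export
#' @examples
#' count_tokens("miR-21 represses PTEN")
count_tokens <- function(text) {
  if (length(text) == 0) return(0L)
  text <- stringr::str_trim(paste(text, collapse = " "))
  if (!nzchar(text)) return(0L)
  length(stringr::str_split_1(text, "\\s+"))
}

CANONICAL_LABELS <- c("abstract", "introduction", "methods", "results", "discussion")

#' Context budget for one curation run
#'
#' Caps on the amount of article text a run may load: `max_context_tokens`
#' bounds the cumulative text ever charged to the run's context (64k tokens
#' by default, matching single-GPU inference limits for 32B-class reasoning
#' models), and `max_evidence_source_tokens` bounds the text offered to the
#' backend for verbatim evidence-span extraction (substring sampling over
#' long sources is the expensive constrained-decoding operation).
#'
#' @param max_context_tokens Positive integer, default 64000.
#' @param max_evidence_source_tokens Positive integer no greater than
#'   `max_context_tokens`, default 4000.
#' @return A `context_budget` list.
#' @export
context_budget <- function(max_context_tokens = 64000L,
                           max_evidence_source_tokens = 4000L) {
  stopifnot(max_context_tokens > 0, max_evidence_source_tokens > 0)
  if (max_evidence_source_tokens > max_context_tokens) {
    abort("max_evidence_source_tokens must not exceed max_context_tokens")
  }
  structure(
    list(max_context_tokens = as.integer(max_context_tokens),
         max_evidence_source_tokens = as.integer(max_evidence_source_tokens)),
    class = "context_budget"
  )
}

new_article <- function(pmcid, pmid, title, pub_types, sections, abstract) {
  structure(
    list(pmcid = pmcid, pmid = pmid, title = title, pub_types = pub_types,
         sections = sections, abstract = abstract),
    class = "jats_article"
  )
}

#' @export
print.jats_article <- function(x, ...) {
  cat(sprintf("<jats_article> %s (%s): %d sections\n",
              x$pmcid %||% "?", paste(x$pub_types, collapse = ","),
              length(x$sections)))
  for (s in x$sections) {
    cat(sprintf("  %-30s %6d tokens\n", s$heading, count_tokens(s$body)))
  }
  invisible(x)
}

# Depth-first plain-text extraction of a <sec>: paragraphs and nested <sec>
# bodies in document order, nested headings folded into the parent body.
sec_body_text <- function(sec) {
  parts <- character()
  for (child in xml2::xml_children(sec)) {
    nm <- xml2::xml_name(child)
    if (nm == "title") next
    if (nm == "sec") {
      sub_title <- xml2::xml_text(xml2::xml_find_first(child, "./title"))
      sub_body <- sec_body_text(child)
      parts <- c(parts, if (!is.na(sub_title) && nzchar(sub_title)) sub_title, sub_body)
    } else {
      txt <- xml2::xml_text(child)
      if (nzchar(stringr::str_trim(txt))) parts <- c(parts, txt)
    }
  }
  parts
}

#' Parse a JATS full-text XML article
#'
#' Reads a JATS / EuropePMC open-access fulltext XML document into a
#' sectioned article model: top-level `<sec>` blocks of the `<body>` become
#' ordered (heading, body) pairs with tags stripped and whitespace normalized
#' (see [normalize_text()]); nested subsections are concatenated into their
#' parent in document order. Publication types are collected from the
#' `article-type` attribute, `article-categories` subject headings, and
#' retraction-related `related-article` links. Gzipped input is handled
#' transparently by the XML reader.
#'
#' @param xml Path to an XML file, a raw vector, or an XML string.
#' @return A `jats_article` with fields `pmcid`, `pmid`, `title`,
#'   `pub_types`, `sections` (list of `list(heading, body)`), `abstract`.
#' @export
parse_jats <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) {
    abort(paste0("failed to parse article XML: ", conditionMessage(e)))
  })
  root <- xml2::xml_find_first(doc, "//article")
  if (is.na(root)) abort("not a JATS document: no <article> element")

  get_id <- function(type) {
    node <- xml2::xml_find_first(
      doc, sprintf("//front//article-meta/article-id[@pub-id-type='%s']", type))
    if (is.na(node)) NULL else xml2::xml_text(node)
  }
  pmcid <- get_id("pmcid") %||% get_id("pmc")
  if (!is.null(pmcid) && !grepl("^PMC", pmcid)) pmcid <- paste0("PMC", pmcid)
  pmid <- get_id("pmid")

  pub_types <- character()
  at <- xml2::xml_attr(root, "article-type")
  if (!is.na(at)) pub_types <- c(pub_types, at)
  subjects <- xml2::xml_text(xml2::xml_find_all(
    doc, "//front//article-categories//subject"))
  pub_types <- c(pub_types, subjects)
  retraction_links <- xml2::xml_find_all(
    doc, "//related-article[@related-article-type='retraction-forward' or @related-article-type='retracted-article']")
  if (length(retraction_links) > 0) pub_types <- c(pub_types, "retracted-publication")
  pub_types <- unique(pub_types)

  title_node <- xml2::xml_find_first(doc, "//front//title-group/article-title")
  title <- if (is.na(title_node)) "" else normalize_text(xml2::xml_text(title_node))
  abstract_node <- xml2::xml_find_first(doc, "//front//abstract")
  abstract <- if (is.na(abstract_node)) "" else normalize_text(xml2::xml_text(abstract_node))

  body <- xml2::xml_find_first(doc, "//body")
  if (is.na(body)) {
    abort(sprintf("bodyless article%s: nothing to curate",
                  if (is.null(pmcid)) "" else paste0(" ", pmcid)))
  }
  sections <- purrr::map(xml2::xml_find_all(body, "./sec"), function(sec) {
    heading <- xml2::xml_text(xml2::xml_find_first(sec, "./title"))
    heading <- if (is.na(heading)) "" else stringr::str_trim(heading)
    body_txt <- normalize_text(paste(sec_body_text(sec), collapse = "\n"))
    list(heading = heading, body = body_txt)
  })
  if (length(sections) == 0) {
    # body with bare paragraphs and no <sec> structure
    paras <- xml2::xml_text(xml2::xml_find_all(body, "./p"))
    if (length(paras) > 0) {
      sections <- list(list(heading = "", body = normalize_text(paste(paras, collapse = "\n"))))
    }
  }
  new_article(pmcid = pmcid, pmid = pmid, title = title,
              pub_types = pub_types, sections = sections, abstract = abstract)
}

article_headings <- function(article) {
  vapply(article$sections, function(s) s$heading, character(1))
}

#' Map canonical section labels to an article's actual headings
#'
#' Section headings vary wildly across journals ("Results", "RESULTS",
#' "Findings", "MATERIALS AND METHODS", ...). For each canonical label the
#' backend is asked a zero-shot constrained choice among the article's real
#' headings plus the sentinel `"NONE"`; `"NONE"` leaves the label unmapped.
#' No string-similarity heuristic is applied in core: the backend's
#' constrained choice is the sole arbiter, so scripted backends must be given
#' explicit heading answers. The abstract is carried as a dedicated article
#' field and is mapped deterministically without a backend call. A heading
#' already claimed by an earlier label is withheld from later choices, so the
#' index is injective by construction.
#'
#' @param article A `jats_article`.
#' @param backend A backend object (see [scripted_backend()],
#'   [keyword_backend()]).
#' @param labels Canonical labels to resolve (default all five).
#' @return A `section_index`: named list `canonical label -> heading`.
#' @export
normalize_headings <- function(article, backend,
                               labels = CANONICAL_LABELS) {
  if (length(article$sections) == 0) abort("article has no sections to index")
  headings <- article_headings(article)
  index <- list()
  taken <- character()
  for (label in labels) {
    if (label == "abstract") {
      if (nzchar(article$abstract)) index[["abstract"]] <- "[abstract]"
      next
    }
    avail <- setdiff(headings[nzchar(headings)], taken)
    if (length(avail) == 0) next
    req <- choice_request(
      key = paste0("heading:", label),
      prompt = paste0(
        "Select the article section heading that best corresponds to the ",
        "canonical label '", label, "'. If no heading corresponds, answer NONE.\n",
        "Headings: ", paste(avail, collapse = " | ")),
      options = c(avail, "NONE")
    )
    resp <- choose(backend, req)
    if (resp$selected != "NONE") {
      index[[label]] <- resp$selected
      taken <- c(taken, resp$selected)
    }
  }
  structure(index, class = "section_index")
}

#' Create a lazy section cache for one run
#'
#' Holds the per-run context-budget ledger: which canonical sections have
#' been loaded, the text actually charged, and a load log. Repeated loads of
#' the same section return the cached text without double-charging the
#' budget.
#'
#' @param budget A [context_budget()].
#' @return A `section_cache` environment.
#' @export
section_cache <- function(budget = context_budget()) {
  env <- new.env(parent = emptyenv())
  env$budget <- budget
  env$loaded <- list()
  env$tokens_used <- 0L
  env$log <- list()
  class(env) <- "section_cache"
  env
}

#' Tokens charged so far in a cache
#' @param cache A `section_cache`.
#' @return Integer token count.
#' @export
tokens_used <- function(cache) cache$tokens_used

#' The per-run section load log
#' @param cache A `section_cache`.
#' @return A tibble with columns `label`, `tokens`, `cached`, `fallback`,
#'   `truncated`.
#' @export
load_log <- function(cache) {
  purrr::map_dfr(cache$log, as_tibble)
}

# Greedy paragraph packing: longest prefix of whole paragraphs whose token
# total fits `limit`. Always yields at least the first paragraph truncated by
# words if even that does not fit.
truncate_to_tokens <- function(text, limit, counter = count_tokens) {
  if (counter(text) <= limit) return(list(text = text, truncated = FALSE))
  paras <- stringr::str_split_1(text, "\n")
  kept <- character()
  used <- 0L
  for (p in paras) {
    n <- counter(p)
    if (used + n > limit) break
    kept <- c(kept, p)
    used <- used + n
  }
  if (length(kept) == 0) {
    words <- stringr::str_split_1(stringr::str_trim(paras[[1]]), "\\s+")
    kept <- paste(head(words, max(limit, 0L)), collapse = " ")
  }
  list(text = paste(kept, collapse = "\n"), truncated = TRUE)
}

section_text_for <- function(article, label, index) {
  if (label == "abstract") return(article$abstract)
  heading <- index[[label]]
  if (is.null(heading)) return(NULL)
  for (s in article$sections) {
    if (identical(s$heading, heading)) return(s$body)
  }
  abort(sprintf("section index maps '%s' to heading '%s' absent from article",
                label, heading))
}

#' Load a canonical section lazily under the context budget
#'
#' Returns the text of the canonical section, truncated at a paragraph
#' boundary to fit the remaining context budget, charging the budget only on
#' first load. When the label is absent from the index the configured
#' fallback applies (abstract, then full body, per
#' [mirflow_config()]`$section_fallback`) and the load is flagged as a
#' fallback in the log — never a silent empty success.
#'
#' @param article A `jats_article`.
#' @param label Canonical label.
#' @param index A `section_index` from [normalize_headings()].
#' @param cache A [section_cache()].
#' @param config A [mirflow_config()].
#' @return `list(text, fallback, cached, truncated)`.
#' @export
get_section <- function(article, label, index, cache,
                        config = mirflow_config()) {
  label <- match.arg(label, CANONICAL_LABELS)
  if (!is.null(cache$loaded[[label]])) {
    entry <- cache$loaded[[label]]
    cache$log[[length(cache$log) + 1]] <- list(
      label = label, tokens = 0L, cached = TRUE,
      fallback = entry$fallback, truncated = entry$truncated)
    return(list(text = entry$text, fallback = entry$fallback,
                cached = TRUE, truncated = entry$truncated))
  }
  text <- section_text_for(article, label, index)
  fallback <- FALSE
  if (is.null(text) || !nzchar(text)) {
    fallback <- TRUE
    text <- if (config$section_fallback == "abstract_then_body" && nzchar(article$abstract)) {
      article$abstract
    } else {
      paste(vapply(article$sections, function(s) s$body, character(1)), collapse = "\n")
    }
    if (!nzchar(text)) abort(sprintf("no text available for section '%s' (fallback empty)", label))
  }
  remaining <- cache$budget$max_context_tokens - cache$tokens_used
  if (remaining <= 0) {
    abort(sprintf("context budget exhausted before loading section '%s'", label),
          class = "mirflow_budget_error")
  }
  tr <- truncate_to_tokens(text, remaining)
  charged <- count_tokens(tr$text)
  cache$tokens_used <- cache$tokens_used + charged
  entry <- list(text = tr$text, fallback = fallback, truncated = tr$truncated)
  cache$loaded[[label]] <- entry
  cache$log[[length(cache$log) + 1]] <- list(
    label = label, tokens = charged, cached = FALSE,
    fallback = fallback, truncated = tr$truncated)
  list(text = tr$text, fallback = fallback, cached = FALSE, truncated = tr$truncated)
}
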