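#' The constrained-generation backend contract
#'
#' Every model backend — real or test double — answers two request shapes:
#'
#' * **constrained choice**: given a prompt and a fixed option list, return
#'   exactly one of the options, plus a free-text reasoning trace capped at a
#'   token budget (default 1024 reasoning tokens);
#' * **constrained span**: given a prompt and a source text, return a span
#'   that is a *verbatim* substring of the source, identified by 0-based
#'   half-open character offsets.
#'
#' The guarantees are enforced by shared verifier wrappers ([choose()] and
#' [extract_span()]), never trusted to adapters: an off-list choice or a
#' paraphrased span raises a `mirflow_contract_violation` naming the backend.
#' Two deterministic, model-free backends ship with the package
#' ([scripted_backend()], [keyword_backend()]); a real constrained-decoding
#' adapter can plug in behind the same contract. API-hosted models cannot
#' satisfy it, because constrained decoding needs control of token sampling.
#'
#' @name backend-contract
NULL

DEFAULT_REASONING_CAP <- 1024L

#' Build a constrained-choice request
#'
#' @param key Routing key identifying what is being asked (a flowchart
#'   node id, `"heading:<label>"`, or `"target:<n>"`); scripted and keyword
#'   backends dispatch on it.
#' @param prompt Full prompt text.
#' @param options Non-empty character vector of distinct options.
#' @param reasoning_cap Maximum reasoning tokens (default 1024).
#' @param temperature Sampling temperature; 0 (the default) for
#'   deterministic decoding.
#' @param context Optional: the article text portion of the prompt, kept
#'   separate so rule-based backends can match evidence patterns against
#'   the article rather than against instruction text (node prompts name
#'   the acceptable assays, which must not self-trigger a rule).
#' @return A `choice_request`.
#' @export
choice_request <- function(key, prompt, options,
                           reasoning_cap = DEFAULT_REASONING_CAP,
                           temperature = 0, context = NULL) {
  options <- as.character(options)
  if (length(options) == 0) abort("choice_request: options must be non-empty")
  if (anyDuplicated(options)) abort("choice_request: options must be pairwise distinct")
  if (reasoning_cap <= 0) abort("choice_request: reasoning_cap must be positive")
  if (temperature < 0) abort("choice_request: temperature must be >= 0")
  structure(
    list(key = key, prompt = prompt, options = options,
         reasoning_cap = as.integer(reasoning_cap), temperature = temperature,
         context = context),
    class = "choice_request"
  )
}

#' Build a constrained-span request
#'
#' The source is truncated to `max_source_tokens` (at a paragraph boundary)
#' before being offered to the backend; offsets in the response index into
#' that truncated source.
#'
#' @param key Routing key (usually the flowchart node id).
#' @param prompt Instruction text.
#' @param source Text the span must be extracted from, verbatim.
#' @param max_source_tokens Cap on the source text offered (default 4000).
#' @param max_span_chars Cap on span length in characters (default 600).
#' @return A `span_request` whose `source` is already truncated.
#' @export
span_request <- function(key, prompt, source,
                         max_source_tokens = 4000L,
                         max_span_chars = 600L) {
  if (max_source_tokens <= 0 || max_span_chars <= 0) {
    abort("span_request: caps must be positive")
  }
  source <- truncate_to_tokens(source, max_source_tokens)$text
  if (!nzchar(stringr::str_trim(source))) {
    abort("span_request: source empty after truncation")
  }
  structure(
    list(key = key, prompt = prompt, source = source,
         max_source_tokens = as.integer(max_source_tokens),
         max_span_chars = as.integer(max_span_chars)),
    class = "span_request"
  )
}

contract_violation <- function(backend, msg) {
  abort(sprintf("backend contract violation [%s]: %s", backend$name, msg),
        class = "mirflow_contract_violation")
}

#' Ask a backend for a constrained choice
#'
#' Dispatches the request to the backend and verifies the contract on the
#' way back: the selection must be one of the request's options and the
#' reasoning-token count must not exceed the request's cap. Violations raise
#' a `mirflow_contract_violation` and are never silently repaired.
#'
#' @param backend A backend object.
#' @param req A [choice_request()].
#' @return A list `selected`, `reasoning`, `reasoning_tokens_used`.
#' @export
choose <- function(backend, req) {
  stopifnot(inherits(req, "choice_request"))
  resp <- backend_choose(backend, req)
  if (is.null(resp$selected) || !resp$selected %in% req$options) {
    contract_violation(backend, sprintf(
      "selected '%s' is not among the %d offered options (key '%s')",
      resp$selected %||% "<null>", length(req$options), req$key))
  }
  resp$reasoning <- resp$reasoning %||% ""
  resp$reasoning_tokens_used <- as.integer(
    resp$reasoning_tokens_used %||% count_tokens(resp$reasoning))
  if (resp$reasoning_tokens_used > req$reasoning_cap) {
    contract_violation(backend, sprintf(
      "reasoning used %d tokens, cap is %d (key '%s')",
      resp$reasoning_tokens_used, req$reasoning_cap, req$key))
  }
  resp
}

#' Ask a backend for a verbatim evidence span
#'
#' Dispatches to the backend and re-checks, character for character, that
#' `substr(source, start, end)` equals the returned span under 0-based
#' half-open offsets, that the offsets are in range, and that the span
#' respects `max_span_chars`. Paraphrases and off-by-one offsets are rejected
#' with a `mirflow_contract_violation`.
#'
#' @param backend A backend object.
#' @param req A [span_request()].
#' @return A list `span`, `start`, `end`, `reasoning`.
#' @export
extract_span <- function(backend, req) {
  stopifnot(inherits(req, "span_request"))
  resp <- backend_extract_span(backend, req)
  start <- resp$start
  end <- resp$end
  if (is.null(start) || is.null(end) ||
      start < 0 || end <= start || end > nchar(req$source)) {
    contract_violation(backend, sprintf(
      "span offsets [%s,%s) out of range for source of %d chars (key '%s')",
      start %||% "?", end %||% "?", nchar(req$source), req$key))
  }
  actual <- substr(req$source, start + 1, end)
  if (!identical(actual, resp$span)) {
    contract_violation(backend, sprintf(
      "span is not the verbatim source slice at [%d,%d) (key '%s')",
      start, end, req$key))
  }
  if (end - start > req$max_span_chars) {
    contract_violation(backend, sprintf(
      "span of %d chars exceeds max_span_chars %d (key '%s')",
      end - start, req$max_span_chars, req$key))
  }
  resp$reasoning <- resp$reasoning %||% ""
  resp
}

backend_choose <- function(backend, req) UseMethod("backend_choose")
backend_extract_span <- function(backend, req) UseMethod("backend_extract_span")

#' @export
backend_choose.default <- function(backend, req) {
  abort("object is not a mirflow backend")
}
#' @export
backend_extract_span.default <- function(backend, req) {
  abort("object is not a mirflow backend")
}

#' @export
print.mirflow_backend <- function(x, ...) {
  cat(sprintf("<mirflow backend: %s>\n", x$name))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scripted backend: a fully deterministic test double.

#' A scripted backend
#'
#' Answers every request from an explicit script keyed by the request's
#' routing key; an unknown key is an error naming the key — there are no
#' defaults. Script entries are:
#'
#' * a character scalar — the option to select for a choice request;
#' * a list with `start`/`end` (0-based half-open offsets into the truncated
#'   source) for a span request; the span text is sliced from the source, so
#'   well-formed entries always satisfy the contract. An entry may instead
#'   supply `span` text directly (with or without offsets), which allows
#'   constructing adversarial doubles that the verifier must reject.
#'
#' Replays byte-identically: the same script always yields the same
#' responses.
#'
#' @param script Named list of entries as above.
#' @param name Backend name used in error messages (default `"scripted"`).
#' @return A backend object.
#' @export
scripted_backend <- function(script, name = "scripted") {
  stopifnot(is.list(script))
  structure(list(name = name, script = script),
            class = c("scripted_backend", "mirflow_backend"))
}

script_entry <- function(backend, key) {
  if (!key %in% names(backend$script)) {
    abort(sprintf("scripted backend [%s] has no entry for key '%s'",
                  backend$name, key))
  }
  backend$script[[key]]
}

#' @export
backend_choose.scripted_backend <- function(backend, req) {
  entry <- script_entry(backend, req$key)
  if (is.list(entry)) {
    list(selected = entry$selected, reasoning = entry$reasoning %||% "",
         reasoning_tokens_used = entry$reasoning_tokens_used)
  } else {
    list(selected = as.character(entry),
         reasoning = sprintf("scripted answer for '%s'", req$key))
  }
}

#' @export
backend_extract_span.scripted_backend <- function(backend, req) {
  entry <- script_entry(backend, req$key)
  if (!is.list(entry)) {
    abort(sprintf("scripted backend [%s]: entry for '%s' is not a span entry",
                  backend$name, req$key))
  }
  span <- entry$span
  if (is.null(span) && !is.null(entry$start) && !is.null(entry$end)) {
    span <- substr(req$source, entry$start + 1, entry$end)
  }
  list(span = span, start = entry$start, end = entry$end,
       reasoning = entry$reasoning %||% sprintf("scripted span for '%s'", req$key))
}

# ---------------------------------------------------------------------------
# Keyword backend: an ordered rule table standing in for a reasoning model.

#' A keyword-rule backend
#'
#' A deterministic rule table standing in for a reasoning LLM, so that
#' engine tests measure plumbing rather than language understanding. Rules
#' are matched **in order** — ordering is semantics, the first applicable
#' rule wins. Each rule is a list with:
#'
#' * `scope`: the routing keys it applies to — exact key, or a prefix
#'   wildcard like `"target*"`;
#' * `pattern`: a regular expression;
#' * `answer` (optional): for yes/no-style rules, the option returned when
#'   `pattern` matches the request prompt. When `answer` is absent the rule
#'   is *option-selecting*: if `pattern` contains the placeholder
#'   `{option}`, each option is substituted into the pattern and tested
#'   against the prompt (first option whose substituted pattern matches
#'   wins); otherwise the pattern is tested against the option text itself
#'   (first matching option wins).
#'
#' When no rule fires the default answer is `"no"` when offered, else
#' `"NONE"`, else `"DONE"`, else the first option. For span requests the
#' backend returns the first sentence of the source that matches the first
#' in-scope rule's pattern, or the first sentence when nothing matches.
#'
#' @param rules List of rule lists, or `NULL` for [default_keyword_rules()].
#' @param name Backend name (default `"keyword"`).
#' @return A backend object.
#' @export
keyword_backend <- function(rules = NULL, name = "keyword") {
  rules <- rules %||% default_keyword_rules()
  for (r in rules) {
    if (is.null(r$scope) || is.null(r$pattern)) {
      abort("keyword rule needs scope and pattern")
    }
    # fail fast on invalid regexes (placeholder substituted with a dummy)
    tryCatch(
      suppressWarnings(grepl(sub("\\{option\\}", "X", r$pattern), "x", perl = TRUE)),
      error = function(e) abort(sprintf(
        "keyword rule pattern '%s' is not a valid regex", r$pattern)))
  }
  structure(list(name = name, rules = rules),
            class = c("keyword_backend", "mirflow_backend"))
}

scope_matches <- function(scope, key) {
  if (endsWith(scope, "*")) {
    startsWith(key, substr(scope, 1, nchar(scope) - 1))
  } else {
    identical(scope, key)
  }
}

keyword_rules_for <- function(backend, key) {
  purrr::keep(backend$rules, function(r) scope_matches(r$scope, key))
}

#' @export
backend_choose.keyword_backend <- function(backend, req) {
  haystack <- req$context %||% req$prompt
  for (r in keyword_rules_for(backend, req$key)) {
    if (!is.null(r$answer)) {
      if (grepl(r$pattern, haystack, perl = TRUE)) {
        return(list(selected = r$answer,
                    reasoning = sprintf("rule '%s' matched prompt for '%s'",
                                        r$pattern, req$key)))
      }
    } else if (grepl("\\{option\\}", r$pattern)) {
      for (opt in req$options) {
        if (opt %in% c("NONE", "DONE", "NOT_IN_LIST")) next
        opt_rx <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", opt)
        pat <- gsub("{option}", opt_rx, r$pattern, fixed = TRUE)
        if (grepl(pat, haystack, perl = TRUE)) {
          return(list(selected = opt,
                      reasoning = sprintf("option '%s' matched context rule for '%s'",
                                          opt, req$key)))
        }
      }
    } else {
      for (opt in req$options) {
        if (identical(opt, "NONE")) next
        if (grepl(r$pattern, opt, perl = TRUE)) {
          return(list(selected = opt,
                      reasoning = sprintf("option '%s' matched '%s' for '%s'",
                                          opt, r$pattern, req$key)))
        }
      }
    }
  }
  default <- if ("no" %in% req$options) "no"
             else if ("NONE" %in% req$options) "NONE"
             else if ("DONE" %in% req$options) "DONE"
             else req$options[[1]]
  list(selected = default,
       reasoning = sprintf("no rule matched for '%s'; default '%s'", req$key, default))
}

# 0-based half-open offsets of the sentence containing position `pos`
# (1-based). Sentences end at '.', '!' or '?' followed by space/newline/EOS.
sentence_bounds <- function(text, pos) {
  ends <- stringr::str_locate_all(text, "[.!?](?=\\s|$)")[[1]][, "start"]
  start <- 1L
  for (e in ends) {
    if (e < pos) start <- e + 1L else break
  }
  end <- nchar(text)
  for (e in ends) {
    if (e >= pos) { end <- e; break }
  }
  while (start <= nchar(text) && substr(text, start, start) %in% c(" ", "\n")) {
    start <- start + 1L
  }
  c(start = start, end = end)
}

#' @export
backend_extract_span.keyword_backend <- function(backend, req) {
  pos <- NA_integer_
  matched <- NULL
  rule_key <- sub("^span:", "", req$key)
  for (r in keyword_rules_for(backend, rule_key)) {
    if (grepl("\\{option\\}", r$pattern)) next
    loc <- stringr::str_locate(req$source, stringr::regex(r$pattern))
    if (!is.na(loc[1, "start"])) {
      pos <- loc[1, "start"]
      matched <- r$pattern
      break
    }
  }
  if (is.na(pos)) pos <- 1L
  b <- sentence_bounds(req$source, pos)
  start0 <- b[["start"]] - 1L
  end0 <- min(b[["end"]], start0 + req$max_span_chars)
  list(span = substr(req$source, start0 + 1, end0),
       start = start0, end = end0,
       reasoning = if (is.null(matched)) {
         sprintf("no pattern matched for '%s'; first sentence returned", req$key)
       } else {
         sprintf("sentence containing first match of '%s'", matched)
       })
}

#' The default keyword rule table
#'
#' The documented rule vocabulary aligned with the evidence classes the
#' synthetic corpus embeds: luciferase 3'UTR reporter assays (functional
#' interaction), qRT-PCR mRNA decrease (destabilization), western-blot
#' protein decrease with unchanged mRNA (translational inhibition),
#' polycistronic cluster phrasing (cluster triage), plus heading-selection
#' and luciferase-context target rules. Also shipped as JSON at
#' `system.file("extdata", "keyword_rules.json", package = "mirflow")`.
#'
#' @return A list of rules suitable for [keyword_backend()].
#' @export
default_keyword_rules <- function() {
  list(
    list(scope = "binding_filter",
         pattern = "(?i)(luciferase|immunoprecipitation|pull-down|reporter assay|CRISPR)",
         answer = "yes"),
    list(scope = "cluster_filter",
         pattern = "(?i)(miRNA cluster|polycistronic)",
         answer = "yes"),
    list(scope = "reporter_assay",
         pattern = "(?i)luciferase reporter",
         answer = "yes"),
    list(scope = "mrna_level",
         pattern = "(?i)mRNA levels? decreased",
         answer = "yes"),
    list(scope = "protein_level",
         pattern = "(?i)protein levels? were markedly reduced[\\s\\S]*mRNA levels? remained unchanged",
         answer = "yes"),
    list(scope = "heading:introduction", pattern = "(?i)(introduction|background)"),
    list(scope = "heading:methods", pattern = "(?i)(method|procedure|experimental)"),
    list(scope = "heading:results", pattern = "(?i)(result|finding)"),
    list(scope = "heading:discussion", pattern = "(?i)(discussion|concluding)"),
    list(scope = "target:*", pattern = "(?i)luciferase[^.]*\\b{option}\\b")
  )
}

#' Load keyword rules from a JSON file
#'
#' @param path Path to a JSON array of rule objects
#'   (`scope`, `pattern`, optional `answer`).
#' @return A rule list for [keyword_backend()].
#' @export
load_keyword_rules <- function(path) {
  jsonlite::read_json(path)
}
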