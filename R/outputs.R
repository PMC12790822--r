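#' Record serialization and exports
#'
#' Curation records are the audit artefact of a run; they serialize to
#' JSONL (one record per line, UTF-8) and round-trip losslessly. Final
#' annotations additionally export as GPAD 2.0, and annotated records as a
#' reviewer-question export for human evaluation.
#'
#' @name outputs
NULL

record_json <- function(record, drop_timestamp = FALSE) {
  x <- unclass(record)
  if (drop_timestamp) x$run_metadata$timestamp <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Compare two records ignoring the run timestamp
#'
#' @param a,b `curation_record` objects.
#' @return `TRUE` when the serialized forms are byte-identical modulo the
#'   `run_metadata$timestamp` field.
#' @export
records_identical <- function(a, b) {
  identical(as.character(record_json(a, drop_timestamp = TRUE)),
            as.character(record_json(b, drop_timestamp = TRUE)))
}

#' Write curation records as JSONL
#'
#' @param records List of `curation_record` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) as.character(record_json(r)), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read curation records from JSONL
#'
#' @param path Path written by [write_records()].
#' @return List of `curation_record` objects.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  purrr::map(lines, function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    x$target_rounds <- as.character(unlist(x$target_rounds))
    structure(x, class = "curation_record")
  })
}

GPAD_COLUMNS <- c("DB_Object_ID", "Negation", "Relation", "Ontology_Class_ID",
                  "Reference", "Evidence_type", "With_or_From",
                  "Interacting_taxon_ID", "Date", "Assigned_by",
                  "Annotation_Extensions", "Annotation_Properties")

#' Validate one GPAD 2.0 line
#'
#' Checks the exact 12-column tab-separated layout and the field syntax of
#' every annotation line this package emits: a URS_taxid subject, an RO
#' relation, a `GO:\\d{7}` class, a `PMID:` reference, an `ECO:\\d{7}`
#' evidence type, an ISO date, and a non-empty `Assigned_by`. Header lines
#' (starting `!`) are valid by definition.
#'
#' @param line A single line, without trailing newline.
#' @return Character vector of violations; empty when the line conforms.
#' @export
validate_gpad_line <- function(line) {
  if (startsWith(line, "!")) return(character())
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field; pad to declared width
  length(fields) <- max(length(fields), length(GPAD_COLUMNS))
  fields[is.na(fields)] <- ""
  v <- character()
  n_tabs <- stringr::str_count(line, stringr::fixed("\t"))
  if (n_tabs != length(GPAD_COLUMNS) - 1) {
    return(sprintf("expected %d tab-separated columns, found %d",
                   length(GPAD_COLUMNS), n_tabs + 1))
  }
  checks <- list(
    DB_Object_ID = "^(RNAcentral:)?URS[0-9A-F]{10}_\\d+$",
    Relation = "^[A-Za-z]+:\\d+$",
    Ontology_Class_ID = "^GO:\\d{7}$",
    Reference = "^PMID:\\d+$",
    Evidence_type = "^ECO:\\d{7}$",
    Date = "^\\d{4}-\\d{2}-\\d{2}$"
  )
  names(fields) <- GPAD_COLUMNS
  for (col in names(checks)) {
    if (!grepl(checks[[col]], fields[[col]])) {
      v <- c(v, sprintf("%s '%s' fails pattern %s", col, fields[[col]], checks[[col]]))
    }
  }
  if (!nzchar(fields[["Assigned_by"]])) v <- c(v, "Assigned_by is empty")
  if (nzchar(fields[["Negation"]]) && fields[["Negation"]] != "NOT") {
    v <- c(v, "Negation must be empty or NOT")
  }
  v
}

#' Write annotated records as GPAD 2.0
#'
#' Emits the `!gpad-version: 2.0` header and one line per annotation from
#' every record with status `annotated`, a resolved URS_taxid and a PMID.
#' The target gene travels in the annotation-extensions column under the
#' configured relation (`RO:0002233`, has input, by default), as
#' `UniProtKB:<accession>` when mapped and the bare symbol otherwise.
#' Records missing the URS or PMID are skipped with a warning — a malformed
#' line is never written.
#'
#' @param records List of `curation_record` objects.
#' @param path Output file path.
#' @param config A [mirflow_config()].
#' @param date Run date stamped in the Date column (default today).
#' @return `path`, invisibly.
#' @export
write_gpad <- function(records, path, config = mirflow_config(),
                       date = format(Sys.Date(), "%Y-%m-%d")) {
  lines <- c("!gpad-version: 2.0",
             paste0("!generated-by: ", config$assigned_by))
  for (r in records) {
    if (!identical(r$status, "annotated")) next
    urs <- r$mirna$urs_taxid
    pmid <- r$pmid
    if (is.null(urs) || is.na(urs %||% NA) || is.null(pmid)) {
      warn(sprintf("skipping record %s in GPAD export: missing %s",
                   r$pmcid %||% "?",
                   if (is.null(urs)) "resolved URS_taxid" else "PMID"))
      next
    }
    for (a in r$annotations) {
      target <- if (!is.null(a$target_accession) && !is.na(a$target_accession)) {
        paste0("UniProtKB:", a$target_accession)
      } else {
        a$target_symbol
      }
      fields <- c(
        urs, "", a$relation, a$go_term, paste0("PMID:", pmid),
        a$evidence_code, "", "", date, a$assigned_by,
        paste0(config$extension_relation, "(", target, ")"), "")
      line <- paste(fields, collapse = "\t")
      bad <- validate_gpad_line(line)
      if (length(bad) > 0) {
        warn(sprintf("skipping malformed GPAD line for %s: %s",
                     r$pmcid %||% "?", paste(bad, collapse = "; ")))
        next
      }
      lines <- c(lines, line)
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate a GPAD file line by line
#'
#' @param path Path to a GPAD file.
#' @return A tibble `line`, `text`, `violation` with one row per violation;
#'   zero rows when the file conforms.
#' @export
validate_gpad_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  for (i in seq_along(lines)) {
    for (v in validate_gpad_line(lines[[i]])) {
      out[[length(out) + 1]] <- tibble(line = i, text = lines[[i]], violation = v)
    }
  }
  if (length(out) == 0) {
    tibble(line = integer(), text = character(), violation = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' The reviewer question set
#'
#' The four questions human curators answer for every annotated record.
#'
#' @return Named character vector of the four questions.
#' @export
review_questions <- function() {
  c(reasoning_ok = "Does the reasoning from the model address the questions well?",
    evidence_ok = "Does the provided evidence support the decisions given for the questions?",
    annotation_ok = "Is the final annotation correct?",
    targets_ok = "Are all targets identified correctly?")
}

#' Export annotated records for human review
#'
#' One review item per annotated record: the rendered per-node trace
#' (question key, answer, reasoning, evidence span) plus the four reviewer
#' questions, pre-filled unanswered, and a free-text comment field. Written
#' as tool-agnostic JSONL.
#'
#' @param records List of `curation_record` objects.
#' @param path Optional output path; when supplied the items are written as
#'   JSONL.
#' @return A list of review items (invisibly when `path` is given).
#' @export
export_review <- function(records, path = NULL) {
  items <- purrr::map(
    purrr::keep(records, function(r) identical(r$status, "annotated")),
    function(r) {
      trace <- purrr::map(r$decisions, function(d) {
        list(node_id = d$node_id, answer = d$answer, reasoning = d$reasoning,
             evidence = if (is.null(d$evidence)) NA else d$evidence$span)
      })
      questions <- purrr::map(as.list(review_questions()), function(q) {
        list(question = q, answer = NULL)
      })
      list(pmcid = r$pmcid, trace = trace,
           annotations = r$annotations,
           questions = questions, comment = NULL)
    })
  if (!is.null(path)) {
    lines <- vapply(items, function(it) {
      as.character(jsonlite::toJSON(it, auto_unbox = TRUE, null = "null"))
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
    return(invisible(items))
  }
  items
}

#' Summarize a set of curation records
#'
#' @param records List of `curation_record` objects.
#' @return A `run_summary`: list with `status_tallies` (tibble `status`,
#'   `n`), `term_counts` (tibble `go_term`, `n` over annotations),
#'   `taxon_counts` (tibble `taxon`, `n`, keyed by the URS_taxid suffix),
#'   and `articles_processed`.
#' @export
summarize_run <- function(records) {
  statuses <- vapply(records, function(r) r$status, character(1))
  status_tallies <- tibble(status = c("annotated", "filtered", "no_annotation", "error")) |>
    dplyr::mutate(n = vapply(.data$status, function(s) sum(statuses == s),
                             integer(1), USE.NAMES = FALSE))
  anns <- purrr::list_flatten(purrr::map(records, "annotations"))
  term_counts <- if (length(anns) == 0) {
    tibble(go_term = character(), n = integer())
  } else {
    tibble(go_term = vapply(anns, function(a) a$go_term, character(1))) |>
      dplyr::count(.data$go_term)
  }
  taxa <- purrr::map_chr(anns, function(a) {
    s <- a$subject_urs_taxid
    if (is.null(s) || is.na(s %||% NA)) NA_character_ else sub("^.*_", "", s)
  })
  taxon_counts <- if (length(taxa) == 0) {
    tibble(taxon = character(), n = integer())
  } else {
    tibble(taxon = taxa) |> dplyr::filter(!is.na(.data$taxon)) |> dplyr::count(.data$taxon)
  }
  structure(
    list(status_tallies = status_tallies, term_counts = term_counts,
         taxon_counts = taxon_counts, articles_processed = length(records)),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d article(s)\n", x$articles_processed))
  for (i in seq_len(nrow(x$status_tallies))) {
    cat(sprintf("  %-14s %d\n", x$status_tallies$status[[i]], x$status_tallies$n[[i]]))
  }
  if (nrow(x$term_counts) > 0) {
    cat("  annotations by GO term:\n")
    for (i in seq_len(nrow(x$term_counts))) {
      cat(sprintf("    %s  %d\n", x$term_counts$go_term[[i]], x$term_counts$n[[i]]))
    }
  }
  invisible(x)
}

#' Term counts of a summary as a tibble
#' @param x A `run_summary`.
#' @param ... Unused.
#' @return A tibble `go_term`, `n`.
#' @export
tidy.run_summary <- function(x, ...) x$term_counts

#' One-row overview of a summary
#' @param x A `run_summary`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.run_summary <- function(x, ...) {
  tallies <- setNames(as.list(x$status_tallies$n), x$status_tallies$status)
  dplyr::bind_cols(
    tibble(articles_processed = x$articles_processed,
           n_annotations = sum(x$term_counts$n)),
    as_tibble(tallies))
}

#' Plot a run summary
#'
#' Bar charts of status tallies and per-term annotation counts.
#'
#' @param object A `run_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.run_summary <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for autoplot()")
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(object$status_tallies, key = "status"),
                  panel = "article status"),
    dplyr::mutate(dplyr::rename(object$term_counts, key = "go_term"),
                  panel = "annotations by GO term"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
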