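sample_records <- function(n_annotated = 2, n_other = 1, seed = 30) {
  outcomes <- c(rep("term_0035279", n_annotated),
                rep("filtered_no_binding", n_other))
  purrr::imap(outcomes, function(o, i) {
    curate_synth_entry(generate_article(synth_spec(o, seed = seed + i)))
  })
}

test_that("JSONL record export round-trips losslessly", {
  recs <- sample_records(2, 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records(recs, path)
  expect_length(readLines(path), 3)
  back <- read_records(path)
  expect_length(back, 3)
  for (i in seq_along(recs)) {
    expect_true(records_identical(recs[[i]], back[[i]]))
  }
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_records(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # UTF-8 survives byte-exact
  rec <- recs[[1]]
  rec$failure_note <- "évidence – ≤1024 jetons"
  write_records(list(rec), path)
  expect_identical(read_records(path)[[1]]$failure_note, rec$failure_note)

  write_records(list(), path)
  expect_identical(readLines(path), character())
  expect_length(read_records(path), 0)
})

test_that("GPAD export emits |payload| x |targets| conformant lines", {
  entry <- generate_article(synth_spec("term_0035278", seed = 55,
                                       targets = c("PTEN", "SMAD4", "TP53")))
  rec <- curate_synth_entry(entry)
  expect_identical(rec$status, "annotated")
  path <- withr::local_tempfile(fileext = ".gpad")
  write_gpad(list(rec), path)
  lines <- readLines(path)
  expect_identical(lines[[1]], "!gpad-version: 2.0")
  data_lines <- lines[!startsWith(lines, "!")]
  expect_length(data_lines, 2L * 3L)
  expect_identical(nrow(validate_gpad_file(path)), 0L)
  for (l in data_lines) {
    expect_identical(length(strsplit(l, "\t")[[1]]) +
                       as.integer(endsWith(l, "\t")), 12L)
  }

  # no annotated records: header-only, still valid
  only_filtered <- sample_records(0, 2)
  write_gpad(only_filtered, path)
  expect_true(all(startsWith(readLines(path), "!")))
  expect_identical(nrow(validate_gpad_file(path)), 0L)
})

test_that("the GPAD line validator rejects malformed lines", {
  good <- paste(c("URS00000001A1_9606", "", "RO:0002331", "GO:0035279",
                  "PMID:1", "ECO:0000501", "", "", "2026-01-01", "x",
                  "RO:0002233(UniProtKB:P1)", ""), collapse = "\t")
  expect_length(validate_gpad_line(good), 0)
  expect_match(validate_gpad_line(sub("GO:0035279", "GO:35279", good)),
               "Ontology_Class_ID", all = FALSE)
  expect_match(validate_gpad_line(sub("PMID:1", "PMC:1", good)),
               "Reference", all = FALSE)
  expect_match(validate_gpad_line(paste(good, "extra", sep = "\t")),
               "columns", all = FALSE)
  expect_match(validate_gpad_line("URS1\tonly three\tcolumns"),
               "columns", all = FALSE)
})

test_that("records without a resolved URS are skipped with a warning, never malformed", {
  rec <- curate_synth_entry(generate_article(synth_spec("term_0035279", seed = 77)),
                            urs = c(`no-such-mirna` = "URS00000009Z9_1"))
  path <- withr::local_tempfile(fileext = ".gpad")
  expect_warning(write_gpad(list(rec), path), "skipping")
  expect_identical(nrow(validate_gpad_file(path)), 0L)
})

test_that("review export asks exactly the four reviewer questions, unanswered", {
  recs <- sample_records(2, 1)
  items <- export_review(recs)
  expect_length(items, 2) # filtered records produce no item
  expected <- c("Does the reasoning from the model address the questions well?",
                "Does the provided evidence support the decisions given for the questions?",
                "Is the final annotation correct?",
                "Are all targets identified correctly?")
  for (it in items) {
    expect_identical(unname(vapply(it$questions, function(q) q$question,
                                   character(1))),
                     expected)
    expect_true(all(vapply(it$questions, function(q) is.null(q$answer), logical(1))))
    expect_gt(length(it$trace), 0)
  }
  path <- withr::local_tempfile(fileext = ".jsonl")
  more <- sample_records(4, 0, seed = 60)
  export_review(more, path)
  expect_length(readLines(path), 4)
})

test_that("run summaries tally statuses, terms and taxa consistently", {
  recs <- c(sample_records(2, 1, seed = 40),
            list(curate_synth_entry(generate_article(
              synth_spec("no_annotation", seed = 44)))))
  s <- summarize_run(recs)
  expect_identical(s$articles_processed, 4L)
  expect_identical(sum(s$status_tallies$n), s$articles_processed)
  expect_identical(s$status_tallies$n[s$status_tallies$status == "annotated"], 2L)
  expect_identical(s$status_tallies$n[s$status_tallies$status == "no_annotation"], 1L)

  # per-term counts equal a manual recount over the records
  manual <- table(unlist(lapply(recs, function(r) {
    vapply(r$annotations, function(a) a$go_term, character(1))
  })))
  for (term in names(manual)) {
    expect_identical(s$term_counts$n[s$term_counts$go_term == term],
                     as.integer(manual[[term]]))
  }
  # per-taxon counts keyed by the URS suffix, recounted independently
  manual_taxa <- table(unlist(lapply(recs, function(r) {
    vapply(r$annotations, function(a) sub("^.*_", "", a$subject_urs_taxid),
           character(1))
  })))
  for (tx in names(manual_taxa)) {
    expect_identical(s$taxon_counts$n[s$taxon_counts$taxon == tx],
                     as.integer(manual_taxa[[tx]]))
  }

  empty <- summarize_run(list())
  expect_identical(empty$articles_processed, 0L)
  expect_identical(sum(empty$status_tallies$n), 0L)

  # additivity under corpus concatenation
  a <- recs[1:2]; b <- recs[3:4]
  sa <- summarize_run(a); sb <- summarize_run(b); sab <- summarize_run(c(a, b))
  expect_identical(sab$status_tallies$n, sa$status_tallies$n + sb$status_tallies$n)
  joined <- dplyr::full_join(sa$term_counts, sb$term_counts, by = "go_term")
  joined[is.na(joined)] <- 0L
  expect_identical(
    dplyr::arrange(sab$term_counts, go_term)$n,
    as.integer(dplyr::arrange(joined, go_term)$n.x +
                 dplyr::arrange(joined, go_term)$n.y))
})

test_that("tidy, glance and autoplot surfaces work on summaries and records", {
  recs <- sample_records(1, 1, seed = 70)
  s <- summarize_run(recs)
  expect_s3_class(tidy(s), "tbl_df")
  g <- glance(s)
  expect_identical(g$articles_processed, 2L)
  td <- tidy(recs[[1]])
  expect_true(all(c("node_id", "answer", "has_evidence") %in% names(td)))
  expect_s3_class(glance(recs[[1]]), "tbl_df")
  skip_if_not_installed("ggplot2")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
})
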