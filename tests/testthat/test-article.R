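test_that("JATS parsing preserves headings, order and pub types", {
  xml <- make_jats(list(Background = "Intro text.",
                        `MATERIALS AND METHODS` = "Cells were cultured.",
                        Findings = "We observed repression."))
  art <- parse_jats(xml)
  expect_identical(vapply(art$sections, function(s) s$heading, character(1)),
                   c("Background", "MATERIALS AND METHODS", "Findings"))
  expect_identical(art$pmcid, "PMC7777777")
  expect_identical(art$pmid, "77777777")
  expect_true("research-article" %in% art$pub_types)

  review <- parse_jats(make_jats(list(Overview = "A review."),
                                 article_type = "review-article"))
  expect_true("review-article" %in% review$pub_types)
})

test_that("nested <sec> blocks concatenate into the parent in document order", {
  xml <- paste0(
    '<article article-type="research-article"><front><article-meta>',
    '<article-id pub-id-type="pmcid">PMC1</article-id>',
    '</article-meta></front><body>',
    '<sec><title>Results</title><p>First paragraph.</p>',
    '<sec><title>Subsection A</title><p>Alpha text.</p></sec>',
    '<sec><title>Subsection B</title><p>Beta text.</p></sec>',
    '<p>Closing paragraph.</p></sec>',
    '</body></article>')
  art <- parse_jats(xml)
  expect_length(art$sections, 1)
  # oracle: independent depth-first walk over the XML text nodes
  doc <- xml2::read_xml(xml)
  oracle <- xml2::xml_find_all(doc, "//body//p | //body//sec/title")
  oracle_txt <- vapply(oracle, xml2::xml_text, character(1))
  oracle_txt <- oracle_txt[oracle_txt != "Results"]
  body <- art$sections[[1]]$body
  # every text node appears, in order
  pos <- vapply(oracle_txt, function(t) regexpr(t, body, fixed = TRUE)[[1]],
                integer(1))
  expect_true(all(pos > 0))
  expect_identical(pos, sort(pos))
})

test_that("parsing rejects non-XML and bodyless documents", {
  expect_error(parse_jats("this is not xml"), "parse")
  xml <- paste0('<article><front><article-meta>',
                '<article-id pub-id-type="pmcid">PMC99</article-id>',
                '</article-meta></front></article>')
  expect_error(parse_jats(xml), "PMC99")
})

test_that("section bodies never invent characters absent from the XML", {
  for (seed in c(3, 17, 40)) {
    for (outcome in c("term_0035279", "no_annotation", "filtered_cluster")) {
      entry <- generate_article(synth_spec(outcome, seed = seed))
      art <- parse_jats(entry$xml)
      flat_xml <- normalize_text(
        paste(xml2::xml_text(xml2::xml_find_all(
          xml2::read_xml(entry$xml), "//body//p | //body//sec/title")),
          collapse = "\n"))
      for (s in art$sections) {
        for (para in strsplit(s$body, "\n", fixed = TRUE)[[1]]) {
          expect_true(grepl(para, flat_xml, fixed = TRUE))
        }
      }
    }
  }
})

test_that("heading normalization is backend-arbitrated and injective", {
  xml <- make_jats(list(`MATERIALS AND METHODS` = "methods text",
                        RESULTS = "results text"))
  art <- parse_jats(xml)
  sb <- scripted_backend(list(
    "heading:introduction" = "NONE",
    "heading:methods" = "MATERIALS AND METHODS",
    "heading:results" = "RESULTS",
    "heading:discussion" = "NONE"))
  idx <- normalize_headings(art, sb)
  expect_identical(idx$methods, "MATERIALS AND METHODS")
  expect_identical(idx$results, "RESULTS")
  expect_null(idx$introduction)
  expect_identical(idx$abstract, "[abstract]")
  # injectivity over every style the generator produces, with the keyword backend
  for (style in c("canonical", "shouty", "exotic")) {
    entry <- generate_article(synth_spec("term_0035279", seed = 5,
                                         heading_style = style))
    art2 <- parse_jats(entry$xml)
    idx2 <- normalize_headings(art2, keyword_backend())
    mapped <- unlist(idx2[names(idx2) != "abstract"])
    expect_identical(anyDuplicated(mapped), 0L)
    expect_match(idx2$results, "(?i)result|finding", perl = TRUE)
  }
})

test_that("get_section is lazy, idempotent and budget-conserving", {
  entry <- generate_article(synth_spec("term_0035279", seed = 9,
                                       heading_style = "canonical"))
  art <- parse_jats(entry$xml)
  idx <- structure(list(results = "Results", abstract = "[abstract]"),
                   class = "section_index")
  cache <- section_cache(context_budget())
  first <- get_section(art, "results", idx, cache)
  charged <- tokens_used(cache)
  second <- get_section(art, "results", idx, cache)
  expect_identical(first$text, second$text)
  expect_false(first$cached)
  expect_true(second$cached)
  expect_identical(tokens_used(cache), charged)
  log <- load_log(cache)
  expect_identical(sum(log$tokens), charged)
})

test_that("budget truncation cuts at a paragraph boundary (greedy packing oracle)", {
  paras <- sprintf("Paragraph %d with exactly seven words in it.", 1:10)
  xml <- make_jats(list(Results = "placeholder"))
  art <- parse_jats(xml)
  art$sections[[1]]$body <- paste(paras, collapse = "\n")
  idx <- structure(list(results = "Results"), class = "section_index")
  budget <- context_budget(max_context_tokens = 30,
                           max_evidence_source_tokens = 10)
  cache <- section_cache(budget)
  got <- get_section(art, "results", idx, cache)
  # oracle: greedily pack whole paragraphs under the token cap
  counter <- 0; keep <- character()
  for (p in paras) {
    if (counter + count_tokens(p) > 30) break
    keep <- c(keep, p); counter <- counter + count_tokens(p)
  }
  expect_identical(got$text, paste(keep, collapse = "\n"))
  expect_true(got$truncated)
  expect_lte(tokens_used(cache), 30)
})

test_that("an absent section falls back and is flagged, never silently empty", {
  xml <- make_jats(list(Findings = "The finding text."))
  art <- parse_jats(xml)
  idx <- structure(list(abstract = "[abstract]"), class = "section_index")
  cache <- section_cache(context_budget())
  got <- get_section(art, "methods", idx, cache)
  expect_true(got$fallback)
  expect_identical(got$text, art$abstract)
  got_body <- get_section(art, "results", idx, cache,
                          mirflow_config(section_fallback = "body"))
  expect_true(got_body$fallback)
  expect_match(got_body$text, "finding text")
})

test_that("token counting is deterministic, monotone and near-additive", {
  expect_identical(count_tokens(""), 0L)
  expect_identical(count_tokens("miR-21 represses PTEN"),
                   count_tokens("miR-21 represses PTEN"))
  expect_gt(count_tokens("miR-21 represses PTEN"), 0L)
  set.seed(42)
  for (i in 1:50) {
    a <- paste(sample(letters, sample(0:8, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(letters, sample(0:8, 1), replace = TRUE), collapse = " ")
    ab <- paste0(a, b)
    expect_gte(count_tokens(ab), max(count_tokens(a), count_tokens(b)))
    expect_lte(abs(count_tokens(ab) - (count_tokens(a) + count_tokens(b))), 1L)
  }
})
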