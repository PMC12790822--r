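# Shared fixtures and independent oracles for the suite.

fixture_flowchart <- local({
  fc <- NULL
  function() {
    if (is.null(fc)) fc <<- mirna_flowchart()
    fc
  }
})

fixture_urs <- function() {
  load_urs_lookup(system.file("extdata", "synthetic_urs_lookup.tsv",
                              package = "mirflow"))
}

fixture_uniprot <- function() {
  load_uniprot_lookup(system.file("extdata", "synthetic_uniprot_lookup.tsv",
                                  package = "mirflow"))
}

# Independently coded recursive path enumerator: returns a sorted character
# vector, one canonical string per root-to-outcome path. Deliberately written
# with a different style (pure recursion, Map/unlist) from the package's
# accumulator walk so the two cannot share a bug.
oracle_paths <- function(fc) {
  describe_outcome <- function(node) {
    if (node$kind == "terminal") {
      paste0("T:", node$node_id, ":",
             paste(sort(vapply(node$payload, function(p) p$term, character(1))),
                   collapse = "+"))
    } else {
      NULL
    }
  }
  walk <- function(node_id, trail) {
    node <- fc$nodes[[node_id]]
    if (node$kind == "terminal") {
      return(paste0(trail, "|", describe_outcome(node)))
    }
    unlist(Map(function(ans) {
      nxt <- if (ans == "yes") node$yes_next else node$no_next
      t2 <- paste0(trail, node_id, "=", ans, ";")
      if (is.null(nxt)) {
        paste0(t2, "|D:", node$on_fail)
      } else {
        walk(nxt, t2)
      }
    }, c("yes", "no")), use.names = FALSE)
  }
  sort(walk(fc$root, ""))
}

# Same canonical string for a package enumerate_paths() entry.
path_string <- function(p) {
  trail <- if (length(p$answers) == 0) "" else {
    paste0(paste(names(p$answers), p$answers, sep = "=", collapse = ";"), ";")
  }
  out <- if (p$outcome$kind == "terminal") {
    paste0("T:", p$outcome$node_id, ":",
           paste(sort(vapply(p$outcome$payload, function(q) q$term, character(1))),
                 collapse = "+"))
  } else {
    paste0("D:", p$outcome$value)
  }
  paste0(trail, "|", out)
}

# Build a minimal JATS document from named sections (heading -> body text).
make_jats <- function(sections, article_type = "research-article",
                      pmcid = "PMC7777777", pmid = "77777777",
                      abstract = "Abstract text.", body_extra = "") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  secs <- paste(vapply(names(sections), function(h) {
    sprintf("<sec><title>%s</title><p>%s</p></sec>", esc(h), esc(sections[[h]]))
  }, character(1)), collapse = "\n")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<article article-type="%s"><front><article-meta>',
    '<article-id pub-id-type="pmcid">%s</article-id>',
    '<article-id pub-id-type="pmid">%s</article-id>',
    '<title-group><article-title>Test article</article-title></title-group>',
    '<abstract><p>%s</p></abstract>',
    '</article-meta></front><body>\n%s\n%s</body></article>'),
    article_type, pmcid, pmid, esc(abstract), secs, body_extra)
}

# Scripted heading answers for an article whose headings are canonical-cased.
identity_heading_script <- function(headings) {
  out <- list()
  for (label in c("introduction", "methods", "results", "discussion")) {
    hit <- headings[tolower(headings) == label]
    out[[paste0("heading:", label)]] <- if (length(hit) > 0) hit[[1]] else "NONE"
  }
  out
}

# Curate one generated synthetic entry end to end with the keyword backend.
curate_synth_entry <- function(entry, fc = fixture_flowchart(),
                               backend = keyword_backend(),
                               urs = fixture_urs(), up = fixture_uniprot()) {
  art <- parse_jats(entry$xml)
  mentions <- parse_gene_list(entry$mentions)
  curate_article(art, fc, backend, mentions, urs, up)
}

# Does a record match its generator ground truth (status, GO terms, targets)?
matches_ground_truth <- function(entry, record) {
  gt <- entry$ground_truth
  terms <- sort(unique(vapply(record$annotations, function(a) a$go_term, character(1))))
  targets <- sort(unique(vapply(record$annotations, function(a) a$target_symbol, character(1))))
  identical(record$status, gt$status) &&
    identical(terms, sort(gt$go_terms)) &&
    identical(targets, sort(gt$targets))
}

# Cross-test state for the acceptance suite (records produced once, checked
# by several property blocks).
.acceptance_state <- new.env(parent = emptyenv())
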