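#' Corpus-construction filters
#'
#' Articles are only suitable for flowchart curation when they study exactly
#' one miRNA (the flowchart reasons about a single miRNA-target interaction
#' at a time), are primary research articles, and have not been retracted.
#' [filter_article()] applies these rules to one parsed article;
#' [filter_corpus()] composes them over a set.
#'
#' @name corpus-filter
NULL

REVIEW_TYPES <- c("review-article", "review")
RETRACTION_TYPES <- c("retraction", "retracted-publication", "retracted-article")
RESEARCH_TYPES <- c("research-article", "article", "brief-report", "rapid-communication")

article_full_text <- function(article) {
  paste(c(article$title, article$abstract,
          vapply(article$sections, function(s) s$body, character(1))),
        collapse = "\n")
}

#' Screen one article for curability
#'
#' Applies the corpus-construction rules: the article must mention exactly
#' one distinct miRNA identifier (miRBase/MirGeneDB schemes, arms collapsed),
#' must not be a review or a retracted publication, and must carry a
#' recognised research-article publication type. Every violated rule
#' contributes a reason; an article passes iff no reason applies.
#'
#' @param article A `jats_article`.
#' @return A one-row tibble: `pmcid`, `passed`, `reasons` (list-column of
#'   character vectors drawn from `multiple_mirnas`, `no_mirna`,
#'   `review_article`, `retracted`, `not_research`), `distinct_mirnas`,
#'   `mirna_id` (the single normalized id when passed, else `NA`).
#' @export
filter_article <- function(article) {
  mentions <- detect_mirna_ids(article_full_text(article))
  distinct <- unique(mentions$normalized_id)
  reasons <- character()
  if (length(distinct) == 0) reasons <- c(reasons, "no_mirna")
  if (length(distinct) > 1) reasons <- c(reasons, "multiple_mirnas")
  if (any(tolower(article$pub_types) %in% REVIEW_TYPES)) {
    reasons <- c(reasons, "review_article")
  }
  if (any(tolower(article$pub_types) %in% RETRACTION_TYPES)) {
    reasons <- c(reasons, "retracted")
  }
  if (!any(tolower(article$pub_types) %in% RESEARCH_TYPES) &&
      !any(tolower(article$pub_types) %in% c(REVIEW_TYPES, RETRACTION_TYPES))) {
    reasons <- c(reasons, "not_research")
  }
  ok <- length(reasons) == 0
  tibble(
    pmcid = article$pmcid %||% NA_character_,
    passed = ok,
    reasons = list(reasons),
    distinct_mirnas = length(distinct),
    mirna_id = if (ok) distinct[[1]] else NA_character_
  )
}

#' Filter a corpus of articles
#'
#' @param articles List of `jats_article` objects.
#' @return `list(kept = <articles passing all rules>, reports = <tibble with
#'   one row per input article, in input order>)`.
#' @export
filter_corpus <- function(articles) {
  if (length(articles) == 0) {
    return(list(kept = list(),
                reports = tibble(pmcid = character(), passed = logical(),
                                 reasons = list(), distinct_mirnas = integer(),
                                 mirna_id = character())))
  }
  reports <- purrr::map_dfr(articles, filter_article)
  list(kept = articles[reports$passed], reports = reports)
}
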