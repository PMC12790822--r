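#' miRNA identifier detection
#'
#' Detects organism-prefixed miRNA identifiers from the two naming
#' authorities, by documented patterns:
#'
#' * **miRBase**: `<3-4 letter prefix>-(miR|mir|let|lin)-<number><optional
#'   letter variant><optional -N paralog><optional -5p/-3p arm>`, e.g.
#'   `hsa-miR-21-5p`, `mmu-let-7a-1`.
#' * **MirGeneDB**: capitalised `<Prefix>-(Mir|Let|Lin)-<number>` with
#'   optional `-P<N>` paralog and `_5p/_3p/_pre` suffix, e.g. `Hsa-Mir-21`,
#'   `Hsa-Mir-17-P1_5p`.
#'
#' The two schemes are case-disjoint, so every match is attributed to
#' exactly one scheme and matches never overlap. Detection is deliberately
#' strict (precision-first): a matched identifier strongly indicates which
#' database entry the article studies. Free-text aliases and genomic
#' coordinates are out of scope.
#'
#' `normalized_id` lowercases prefix and stem and strips the arm suffix
#' (`-5p`/`-3p`, `_5p`/`_3p`/`_pre`) but keeps letter variants and paralog
#' numbers, so `hsa-miR-21-5p` and `hsa-miR-21-3p` count as one distinct
#' miRNA gene while `hsa-miR-21` and `hsa-miR-22` stay distinct.
#'
#' @param text Character scalar of plain text.
#' @return A tibble with columns `raw_text`, `scheme`, `organism_prefix`,
#'   `normalized_id`, `start`, `end` (1-based match offsets), one row per
#'   raw (non-overlapping) match in text order.
#' @export
#' @examples
#' detect_mirna_ids("hsa-miR-21-5p suppresses PTEN; see also Hsa-Mir-21.")
detect_mirna_ids <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  mirbase_rx <- "\\b([A-Za-z]{3,4})-(miR|mir|let|lin)-(\\d+)([a-z]{1,2})?(-\\d+)?(-[53]p)?\\b"
  mirgenedb_rx <- "\\b([A-Z][a-z]{2,3})-(Mir|Let|Lin)-(\\d+)(-P\\d+)?(_(5p|3p|pre))?\\b"

  collect <- function(rx, scheme) {
    loc <- stringr::str_locate_all(text, rx)[[1]]
    if (nrow(loc) == 0) return(NULL)
    raw <- stringr::str_sub(text, loc[, "start"], loc[, "end"])
    tibble(raw_text = raw, scheme = scheme,
           start = as.integer(loc[, "start"]), end = as.integer(loc[, "end"]))
  }
  hits <- dplyr::bind_rows(
    collect(mirbase_rx, "mirbase"),
    collect(mirgenedb_rx, "mirgenedb")
  )
  if (nrow(hits) == 0) {
    return(tibble(raw_text = character(), scheme = character(),
                  organism_prefix = character(), normalized_id = character(),
                  start = integer(), end = integer()))
  }
  hits <- dplyr::arrange(hits, .data$start)
  hits |>
    dplyr::mutate(
      organism_prefix = tolower(stringr::str_extract(.data$raw_text, "^[A-Za-z]+")),
      normalized_id = normalize_mirna_id(.data$raw_text, .data$scheme)
    ) |>
    dplyr::select("raw_text", "scheme", "organism_prefix", "normalized_id",
                  "start", "end")
}

normalize_mirna_id <- function(raw, scheme) {
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    id <- raw[[i]]
    if (scheme[[i]] == "mirbase") {
      id <- sub("-[53]p$", "", id)
    } else {
      id <- sub("_(5p|3p|pre)$", "", id)
    }
    out[[i]] <- tolower(id)
  }
  out
}

#' Load a miRNA-to-URS lookup table
#'
#' Two-column tab-separated table with header `normalized_id`, `urs_taxid`
#' mapping normalized miRNA gene ids to RNAcentral `URS..._taxid`
#' identifiers. Malformed URS ids and duplicate keys are load-time errors.
#'
#' @param path Path to the TSV file.
#' @return Named character vector `normalized_id -> urs_taxid`.
#' @export
load_urs_lookup <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("normalized_id", "urs_taxid") %in% names(tab))) {
    abort("URS lookup must have columns normalized_id, urs_taxid")
  }
  bad <- !grepl("^URS[0-9A-F]{10}_\\d+$", tab$urs_taxid)
  if (any(bad)) {
    abort(sprintf("malformed urs_taxid in lookup: %s",
                  paste(tab$urs_taxid[bad], collapse = ", ")))
  }
  dup <- tab$normalized_id[duplicated(tab$normalized_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate normalized_id key(s) in lookup: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  setNames(tab$urs_taxid, tab$normalized_id)
}

#' Resolve miRNA mentions to RNAcentral URS_taxid identifiers
#'
#' Joins detected mentions against a URS lookup. A miss is not an error: the
#' mention stays usable with `resolved = FALSE`, but GPAD emission for the
#' record is blocked downstream (annotations of this type are anchored on
#' the URS id).
#'
#' @param mentions A tibble from [detect_mirna_ids()].
#' @param lookup Named vector from [load_urs_lookup()].
#' @return The mentions tibble with `urs_taxid` and `resolved` columns.
#' @export
resolve_urs <- function(mentions, lookup) {
  mentions |>
    dplyr::mutate(
      urs_taxid = unname(lookup[.data$normalized_id]),
      resolved = !is.na(.data$urs_taxid)
    )
}
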