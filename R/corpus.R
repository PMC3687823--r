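# Citation/sentence data model, readers/writers, sentence segmentation.
#
# A corpus is a tibble with one row per citation:
#   citation_id, journal, publication_types (list<chr>), mesh_headings
#   (list<chr>), title, abstract, section_labels (list<tibble(heading,
#   start, end)>), gold_generif (list<int> positions), gold_discourse /
#   gold_claim / gold_subcategory (list<tibble(position, label)>).
# Sentence positions are 1-based; the title is always position 1 and section
# ranges refer to sentence positions (so the first abstract sentence is 2).

FIXTURE_FIELDS <- c("id", "journal", "pubtypes", "mesh", "title", "abstract",
                    "sections", "gold_generif", "gold_discourse",
                    "gold_claim", "gold_subcat")

GOLD_DISCOURSE_LEVELS <- c("Background", "Conclusions", "Methods", "Purpose",
                           "Results", "Title")
GOLD_CLAIM_LEVELS <- c("Established", "Putative", "Non-Claim")
GOLD_SUBCATEGORY_LEVELS <- c("Expression", "Function", "Isolation", "Other",
                             "Reference", "Structure")

empty_citations <- function() {
  tibble(
    citation_id = character(), journal = character(),
    publication_types = list(), mesh_headings = list(),
    title = character(), abstract = character(), section_labels = list(),
    gold_generif = list(), gold_discourse = list(), gold_claim = list(),
    gold_subcategory = list()
  )
}

#' Read citations from a file
#'
#' Reads MEDLINE-style citations from either PubMed citation XML (a subset:
#' PMID, journal title, publication types, MeSH descriptor names, article
#' title, abstract text with optional section labels) or the package's
#' line-oriented fixture dialect (see [write_citations()] for the layout).
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default; sniffs for an XML declaration or root
#'   element), `"fixture"`, or `"pubmed_xml"`.
#' @return A citation tibble, one row per record, in input order. Records
#'   lacking a title are rejected with an error naming the record.
#' @export
read_citations <- function(path, format = c("auto", "fixture", "pubmed_xml")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readr::read_lines(path, n_max = 1, progress = FALSE)
    format <- if (length(first) > 0 && grepl("^\\s*<", first[1]))
      "pubmed_xml" else "fixture"
  }
  switch(format,
    fixture = read_citations_fixture(path),
    pubmed_xml = read_citations_xml(path)
  )
}

# ---- fixture dialect -------------------------------------------------------
# One citation per line; tab-separated `name=value` fields. Multi-valued
# fields use "|" (pubtypes, mesh), ";" (sections as HEADING:start-end), ","
# (gold_generif positions, gold label assignments as position:Label).
# Values must not contain tabs or newlines; the synthetic generator and
# writer guarantee this.

read_citations_fixture <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_citations())
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    kv <- stringr::str_match(parts, "^([a-z_]+)=(.*)$")
    if (anyNA(kv[, 1])) {
      abort(sprintf("record %d: malformed field '%s'", i,
                    parts[which(is.na(kv[, 1]))[1]]))
    }
    unknown <- setdiff(kv[, 2], FIXTURE_FIELDS)
    if (length(unknown) > 0) {
      abort(sprintf("record %d: unknown field '%s'", i, unknown[1]))
    }
    f <- setNames(as.list(kv[, 3]), kv[, 2])
    if (is.null(f$id) || !nzchar(f$id)) {
      abort(sprintf("record %d: missing field 'id'", i))
    }
    if (is.null(f$title) || !nzchar(f$title)) {
      abort(sprintf("record %d: missing field 'title'", i))
    }
    tibble(
      citation_id = f$id,
      journal = f$journal %||% NA_character_,
      publication_types = list(split_multi(f$pubtypes, "|")),
      mesh_headings = list(split_multi(f$mesh, "|")),
      title = f$title,
      abstract = f$abstract %||% "",
      section_labels = list(parse_sections(f$sections, i)),
      gold_generif = list(parse_positions(f$gold_generif)),
      gold_discourse = list(parse_gold_labels(f$gold_discourse,
                                              GOLD_DISCOURSE_LEVELS, i,
                                              "gold_discourse")),
      gold_claim = list(parse_gold_labels(f$gold_claim, GOLD_CLAIM_LEVELS,
                                          i, "gold_claim")),
      gold_subcategory = list(parse_gold_labels(f$gold_subcat,
                                                GOLD_SUBCATEGORY_LEVELS, i,
                                                "gold_subcat"))
    )
  })
  dplyr::bind_rows(rows)
}

split_multi <- function(x, sep) {
  if (is.null(x) || !nzchar(x)) return(character(0))
  strsplit(x, sep, fixed = TRUE)[[1]]
}

parse_sections <- function(x, rec) {
  if (is.null(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("record %d: malformed field 'sections' near '%s'",
                  rec, parts[which(is.na(m[, 1]))[1]]))
  }
  tibble(heading = m[, 2], start = as.integer(m[, 3]),
         end = as.integer(m[, 4]))
}

parse_positions <- function(x) {
  if (is.null(x)) return(NULL)               # annotation absent
  if (!nzchar(x)) return(integer(0))         # annotated, no positives
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

parse_gold_labels <- function(x, levels, rec, field) {
  if (is.null(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts, "^(\\d+):(.+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("record %d: malformed field '%s'", rec, field))
  }
  bad <- setdiff(m[, 3], levels)
  if (length(bad) > 0) {
    abort(sprintf("record %d: field '%s' has label '%s' outside {%s}",
                  rec, field, bad[1], paste(levels, collapse = ", ")))
  }
  tibble(position = as.integer(m[, 2]), label = m[, 3])
}

#' Write citations to the fixture dialect
#'
#' One citation per line as tab-separated `name=value` fields. Reading a
#' fixture file and writing it back is content-identical.
#'
#' @param citations A citation tibble (see [read_citations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_citations <- function(citations, path) {
  lines <- purrr::pmap_chr(citations, function(citation_id, journal,
                                               publication_types,
                                               mesh_headings, title, abstract,
                                               section_labels, gold_generif,
                                               gold_discourse, gold_claim,
                                               gold_subcategory, ...) {
    f <- c(id = citation_id)
    if (!is.na(journal)) f["journal"] <- journal
    if (length(publication_types) > 0)
      f["pubtypes"] <- paste(publication_types, collapse = "|")
    if (length(mesh_headings) > 0)
      f["mesh"] <- paste(mesh_headings, collapse = "|")
    f["title"] <- title
    if (nzchar(abstract)) f["abstract"] <- abstract
    if (!is.null(section_labels) && nrow(section_labels) > 0) {
      f["sections"] <- paste(sprintf("%s:%d-%d", section_labels$heading,
                                     section_labels$start,
                                     section_labels$end), collapse = ";")
    }
    if (!is.null(gold_generif))
      f["gold_generif"] <- paste(gold_generif, collapse = ",")
    for (nm in c("gold_discourse", "gold_claim", "gold_subcat")) {
      g <- switch(nm, gold_discourse = gold_discourse,
                  gold_claim = gold_claim, gold_subcat = gold_subcategory)
      if (!is.null(g) && nrow(g) > 0)
        f[nm] <- paste(sprintf("%d:%s", g$position, g$label), collapse = ",")
    }
    paste(sprintf("%s=%s", names(f), unname(f)), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- PubMed XML subset -----------------------------------------------------

read_citations_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  if (length(arts) == 0) return(empty_citations())
  rows <- purrr::imap(arts, function(art, i) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    if (is.na(title) || !nzchar(trimws(title))) {
      abort(sprintf("record %d: missing field 'ArticleTitle'", i))
    }
    journal <- xml2::xml_text(
      xml2::xml_find_first(art, ".//Journal/Title | .//Journal/JournalTitle"))
    ptypes <- xml2::xml_text(xml2::xml_find_all(art, ".//PublicationType"))
    mesh <- xml2::xml_text(
      xml2::xml_find_all(art, ".//MeshHeading/DescriptorName"))
    chunks <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    texts <- trimws(xml2::xml_text(chunks))
    labels <- xml2::xml_attr(chunks, "Label")
    abstract <- paste(texts[nzchar(texts)], collapse = " ")
    sections <- NULL
    if (length(chunks) > 0 && any(!is.na(labels))) {
      # Sentence ranges computed chunk-wise with the same splitter used by
      # segment_sentences(); positions are 2-based (title occupies 1).
      counts <- vapply(texts, function(t) length(split_into_sentences(t)),
                       integer(1))
      ends <- cumsum(counts) + 1L
      starts <- ends - counts + 1L
      keep <- !is.na(labels) & counts > 0
      if (any(keep)) {
        sections <- tibble(heading = labels[keep],
                           start = unname(starts[keep]),
                           end = unname(ends[keep]))
      }
    }
    tibble(
      citation_id = if (is.na(pmid)) sprintf("record-%d", i) else pmid,
      journal = journal,
      publication_types = list(ptypes), mesh_headings = list(mesh),
      title = trimws(title), abstract = abstract,
      section_labels = list(sections),
      gold_generif = list(NULL), gold_discourse = list(NULL),
      gold_claim = list(NULL), gold_subcategory = list(NULL)
    )
  })
  dplyr::bind_rows(rows)
}

# ---- sentence segmentation -------------------------------------------------

# Abbreviations whose trailing period never ends a sentence.
PROTECTED_ABBREV <- c("e.g", "i.e", "vs", "cf", "et al", "etc", "ca", "no",
                      "approx", "fig", "figs", "dr", "st", "spp", "resp")

# Rule-based splitter: a sentence boundary is terminal punctuation ([.!?])
# followed by whitespace, unless the word before a period is a protected
# abbreviation or a single initial.
split_into_sentences <- function(text) {
  text <- trimws(gsub("\\s+", " ", text))
  if (!nzchar(text)) return(character(0))
  locs <- stringr::str_locate_all(text, "[.!?]+ ")[[1]]
  if (nrow(locs) > 0) {
    keep <- vapply(seq_len(nrow(locs)), function(k) {
      start <- locs[k, 1]
      punct <- substr(text, start, start)
      if (punct != ".") return(TRUE)
      before <- substr(text, max(1, start - 12), start - 1)
      last <- stringr::str_extract(before, "(et al|[A-Za-z]+\\.[A-Za-z]+|[A-Za-z]+)$")
      if (is.na(last)) return(TRUE)
      if (tolower(last) %in% PROTECTED_ABBREV) return(FALSE)
      if (grepl("^[A-Za-z]\\.[A-Za-z]$", last)) return(FALSE)  # e.g. "i.e"
      if (grepl("^[A-Z]$", last)) return(FALSE)                # initials
      TRUE
    }, logical(1))
    locs <- locs[keep, , drop = FALSE]
  }
  if (nrow(locs) == 0) return(text)
  # boundary = end of the punctuation run (locs[,2] includes trailing space)
  ends <- locs[, 2] - 1L   # last punctuation char
  starts <- c(1L, locs[, 2] + 1L)
  stops <- c(ends, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Segment citations into ordered sentences
#'
#' Splits each citation's abstract into sentences with a deterministic
#' rule-based splitter (terminal punctuation plus a protected-abbreviation
#' list, so "i.e." or "Fig." never end a sentence). The title becomes
#' sentence position 1; abstract sentences follow as 2..N. An empty abstract
#' yields the title sentence alone. Gold annotations carried on the citation
#' are attached to their sentences.
#'
#' @param citations A citation tibble from [read_citations()] or
#'   [generate_corpus()].
#' @return A sentence tibble: `citation_id`, `position`, `text`,
#'   `gold_generif` (logical; `NA` when the citation carries no annotation),
#'   `gold_discourse`, `gold_claim`, `gold_subcategory` (character; `NA`
#'   when absent).
#' @export
segment_sentences <- function(citations) {
  rows <- purrr::pmap(citations, function(citation_id, title, abstract,
                                          gold_generif, gold_discourse,
                                          gold_claim, gold_subcategory, ...) {
    if (is.na(title) || !nzchar(trimws(title))) {
      abort(sprintf("citation %s: empty title", citation_id))
    }
    texts <- c(trimws(title), split_into_sentences(abstract %||% ""))
    n <- length(texts)
    pos <- seq_len(n)
    gg <- if (is.null(gold_generif)) NA else pos %in% gold_generif
    lab <- function(g) {
      if (is.null(g)) return(rep(NA_character_, n))
      out <- rep(NA_character_, n)
      ok <- g$position >= 1 & g$position <= n
      out[g$position[ok]] <- g$label[ok]
      out
    }
    tibble(citation_id = citation_id, position = pos, text = texts,
           gold_generif = gg, gold_discourse = lab(gold_discourse),
           gold_claim = lab(gold_claim),
           gold_subcategory = lab(gold_subcategory))
  })
  dplyr::bind_rows(rows)
}
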