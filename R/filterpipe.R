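# Automatable citation-filtering rules from the data-set construction
# pipeline: journal-level species-confound screening, then per-citation
# rules (abstract present, human MeSH, gene mention present, focused
# reviews only, allowed publication types).

#' Default model-species confound terms
#'
#' The eleven common model-species terms whose presence marks a citation as
#' confounded for journal screening.
#'
#' @return Character vector of species terms.
#' @export
default_species_terms <- function() {
  c("mouse", "murine", "yeast", "fly", "drosophila", "cow", "cattle",
    "bovine", "worm", "c. elegans", "plant")
}

# whole-token, case-insensitive search over title + abstract
contains_species_term <- function(text, terms) {
  text <- tolower(text)
  pats <- paste0("(?<![a-z0-9])",
                 vapply(terms, function(t) stringr::str_escape(tolower(t)),
                        character(1)),
                 "(?![a-z0-9])")
  purrr::reduce(pats, function(acc, p) {
    acc | stringr::str_detect(text, stringr::regex(p))
  }, .init = rep(FALSE, length(text)))
}

#' Screen journals by model-species confounding
#'
#' A journal is accepted when strictly fewer than `threshold` of its
#' citations contain at least one model-species term (whole-token,
#' case-insensitive, over title + abstract). Journals with no citations
#' are excluded and reported.
#'
#' @param citations Citation tibble (columns `journal`, `title`,
#'   `abstract`).
#' @param species_terms Confound terms; defaults to the eleven model
#'   species.
#' @param threshold Confounded fraction at or above which a journal is
#'   rejected (default 0.40).
#' @return A tibble, one row per journal: `journal`, `n_citations`,
#'   `n_confounded`, `fraction`, `accepted`.
#' @export
journal_confound_filter <- function(citations,
                                    species_terms = default_species_terms(),
                                    threshold = 0.40) {
  empty <- citations %>% filter(is.na(.data$journal) | !nzchar(.data$journal))
  if (nrow(empty) > 0) {
    inform(sprintf("journal_confound_filter(): %d citation(s) without a journal excluded",
                   nrow(empty)))
  }
  citations %>%
    filter(!is.na(.data$journal) & nzchar(.data$journal)) %>%
    mutate(confounded = contains_species_term(
      paste(.data$title, .data$abstract), species_terms)) %>%
    group_by(.data$journal) %>%
    summarise(n_citations = dplyr::n(),
              n_confounded = sum(.data$confounded), .groups = "drop") %>%
    mutate(fraction = .data$n_confounded / .data$n_citations,
           accepted = .data$fraction < threshold) %>%
    arrange(.data$journal)
}

ALLOWED_PUBTYPES <- c("Journal Article", "Meta-Analysis", "Review")

#' Apply the per-citation filtering rules
#'
#' Applies, in order: (a) drop citations without an abstract; (b) drop
#' citations whose MeSH headings denote a non-human species (a heading on
#' the non-human list present and "Humans" absent); (c) keep only citations
#' with at least one gene mention; (d) drop review-typed citations with
#' three or more distinct resolved gene identifiers (reviews must focus on
#' a particular gene); (e) keep only publication types Journal Article,
#' Meta-Analysis, or Review. Counts reconcile exactly: input = survivors +
#' sum(removed).
#'
#' @param citations Citation tibble.
#' @param mentions Mention tibble from [match_mentions()] (ideally after
#'   disambiguation, for rule (d)'s distinct-gene count).
#' @param nonhuman_mesh Non-human organism MeSH headings; defaults to the
#'   packaged list.
#' @return A `filter_report`: list with `input` (count), `rules` (tibble
#'   `rule`, `removed`), `survivors` (citation tibble), `survivor_ids`.
#' @export
citation_filters <- function(citations, mentions,
                             nonhuman_mesh = default_nonhuman_mesh()) {
  input <- nrow(citations)
  removed <- integer(0)
  drop_rule <- function(df, name, drop) {
    removed[[name]] <<- sum(drop)
    df[!drop, , drop = FALSE]
  }
  cur <- citations
  cur <- drop_rule(cur, "no_abstract",
                   is.na(cur$abstract) | !nzchar(trimws(cur$abstract)))
  nonhuman <- vapply(cur$mesh_headings, function(mh) {
    any(mh %in% nonhuman_mesh) && !"Humans" %in% mh
  }, logical(1))
  cur <- drop_rule(cur, "nonhuman_mesh", nonhuman)
  mention_counts <- mentions %>%
    mutate(gid = ifelse(is.na(.data$resolved_id),
                        purrr::map_chr(.data$candidate_ids, paste,
                                       collapse = "|"),
                        .data$resolved_id)) %>%
    group_by(.data$citation_id) %>%
    summarise(n_mentions = dplyr::n(),
              n_genes = dplyr::n_distinct(.data$gid), .groups = "drop")
  info <- cur %>%
    left_join(mention_counts, by = "citation_id") %>%
    mutate(n_mentions = dplyr::coalesce(.data$n_mentions, 0L),
           n_genes = dplyr::coalesce(.data$n_genes, 0L))
  cur <- drop_rule(cur, "no_gene_mention", info$n_mentions == 0)
  info <- info[info$n_mentions > 0, , drop = FALSE]
  is_review <- vapply(cur$publication_types, function(pt) "Review" %in% pt,
                      logical(1))
  cur <- drop_rule(cur, "unfocused_review", is_review & info$n_genes >= 3)
  allowed <- vapply(cur$publication_types, function(pt) {
    any(pt %in% ALLOWED_PUBTYPES)
  }, logical(1))
  cur <- drop_rule(cur, "publication_type", !allowed)
  structure(
    list(input = input,
         rules = tibble(rule = names(removed),
                        removed = as.integer(removed)),
         survivors = cur, survivor_ids = cur$citation_id),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %d citations in, %d surviving>\n",
              x$input, nrow(x$survivors)))
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %-18s removed %d\n", x$rules$rule[i],
                x$rules$removed[i]))
  }
  invisible(x)
}

#' Write a filter report to a key-value text file
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  lines <- c(sprintf("input\t%d", report$input),
             sprintf("removed_%s\t%d", report$rules$rule,
                     report$rules$removed),
             sprintf("survivors\t%d", nrow(report$survivors)),
             sprintf("survivor_ids\t%s",
                     paste(report$survivor_ids, collapse = ",")))
  readr::write_lines(lines, path)
  invisible(path)
}
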