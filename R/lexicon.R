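# Human gene-name dictionary construction, longest-first mention matching,
# and the two normalization strategies (officialness ranking and
# profile-based disambiguation).

#' Read a gene record table
#'
#' Tab-separated with columns gene_id, symbol, name, synonyms
#' (pipe-separated; "-" or empty for none), mirroring the public gene_info
#' layout.
#'
#' @param path Path to the table. A header line is optional.
#' @return A tibble: `gene_id`, `official_symbol`, `official_name`,
#'   `synonyms` (list of character vectors).
#' @export
read_gene_records <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("gene_id", "official_symbol",
                                             "official_name", "synonyms"),
                         col_types = "cccc", comment = "#", progress = FALSE)
  if (nrow(tab) > 0 && identical(tab$gene_id[1], "gene_id")) {
    tab <- tab[-1, ]
  }
  tab %>%
    mutate(synonyms = purrr::map(.data$synonyms, function(s) {
      if (is.na(s) || s %in% c("", "-")) character(0)
      else strsplit(s, "|", fixed = TRUE)[[1]]
    }))
}

#' Write a gene dictionary to a tab-separated file
#' @param dictionary A dictionary tibble from [build_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_tsv(dictionary, path, progress = FALSE)
  invisible(path)
}

#' Generate punctuation/spacing variants of a gene name
#'
#' Authors vary in how they punctuate gene names. For names containing
#' exactly one dash, two variants are produced: the dash replaced by a
#' space, and the dash removed ("cortexin-2" gives "cortexin 2" and
#' "cortexin2"). Names with zero or multiple dashes produce no variants;
#' the original name is kept by the dictionary builder regardless.
#'
#' @param name A single gene name.
#' @return Character vector of variants (possibly empty).
#' @export
#' @examples
#' generate_variants("cortexin-2")
generate_variants <- function(name) {
  stopifnot(length(name) == 1, nzchar(name))
  n_dash <- stringr::str_count(name, stringr::fixed("-"))
  if (n_dash != 1) return(character(0))
  unique(c(sub("-", " ", name, fixed = TRUE),
           sub("-", "", name, fixed = TRUE)))
}

# officialness ranks: lower is more official
RANK_SYMBOL <- 0L
RANK_NAME <- 1L
RANK_SYNONYM <- 2L

#' Build a gene-name dictionary
#'
#' Collects official symbols, official names, synonyms and their
#' punctuation variants into a surface-form lookup table. Misleading
#' surface forms ending (case-insensitively) in a banned suffix are
#' removed; duplicates are collapsed so a surface form shared by several
#' genes carries all candidate identifiers; entries are ordered longest
#' surface form first (ties lexicographic) so matching finds the longest
#' possible name before any component of it.
#'
#' @param records Gene record tibble (see [read_gene_records()]).
#' @param banned_suffixes Surface forms ending in one of these are dropped.
#' @return A dictionary tibble, one row per (surface form, gene_id):
#'   `surface`, `gene_id`, `rank` (0 official symbol, 1 official name, 2
#'   synonym or variant of one; a surface reachable by several routes keeps
#'   the most official), `nchar`.
#' @export
build_dictionary <- function(records,
                             banned_suffixes = c("disease", "syndrome",
                                                 "susceptibility")) {
  if (is.null(records) || nrow(records) == 0) {
    abort("build_dictionary(): empty gene record set")
  }
  one <- function(gene_id, surface, rank) {
    surface <- surface[!is.na(surface) & nzchar(surface)]
    if (length(surface) == 0) return(NULL)
    forms <- unlist(lapply(surface, function(s) c(s, generate_variants(s))))
    tibble(surface = forms, gene_id = gene_id, rank = rank)
  }
  entries <- purrr::pmap(records, function(gene_id, official_symbol,
                                           official_name, synonyms, ...) {
    dplyr::bind_rows(
      one(gene_id, official_symbol, RANK_SYMBOL),
      one(gene_id, official_name, RANK_NAME),
      one(gene_id, synonyms, RANK_SYNONYM)
    )
  }) %>% dplyr::bind_rows()
  if (length(banned_suffixes) > 0) {
    pat <- paste0("(", paste(tolower(banned_suffixes), collapse = "|"),
                  ")$")
    entries <- entries %>% filter(!grepl(pat, tolower(.data$surface)))
  }
  entries %>%
    group_by(.data$surface, .data$gene_id) %>%
    summarise(rank = min(.data$rank), .groups = "drop") %>%
    mutate(nchar = nchar(.data$surface)) %>%
    arrange(dplyr::desc(.data$nchar), .data$surface, .data$gene_id)
}

#' Ambiguous surface forms of a dictionary
#'
#' Surface forms mapping to more than one gene identifier; the candidate
#' list used to trigger profile-based disambiguation.
#'
#' @param dictionary A dictionary tibble.
#' @return Character vector of ambiguous surface forms.
#' @export
ambiguous_surfaces <- function(dictionary) {
  dictionary %>%
    count(.data$surface) %>%
    filter(.data$n > 1) %>%
    pull(.data$surface)
}

#' Match gene mentions in sentences
#'
#' Greedy leftmost-longest dictionary matching at token boundaries.
#' Matching is case-insensitive except for surface forms on the homonym
#' list (gene symbols doubling as common English words), which must match
#' case-sensitively. Matches never overlap; each mention carries every
#' candidate gene identifier for its surface form. By default matching
#' operates on abbreviation-expanded text (definitions collected per
#' citation), so spans refer to the expanded sentence text returned in the
#' `text` column of the result.
#'
#' @param sentences Sentence tibble from [segment_sentences()] (columns
#'   `citation_id`, `position`, `text`).
#' @param dictionary Dictionary tibble from [build_dictionary()].
#' @param homonyms Character vector of case-sensitive surface forms;
#'   defaults to the packaged list.
#' @param expand Expand parenthetical abbreviations before matching?
#' @return A mention tibble: `citation_id`, `position`, `start`, `end`
#'   (0-based half-open character offsets into the matched text), `text`
#'   (matched span), `candidate_ids` (list of character vectors),
#'   `resolved_id` (`NA` until disambiguated).
#' @export
match_mentions <- function(sentences, dictionary,
                           homonyms = default_homonyms(),
                           expand = TRUE) {
  empty <- tibble(citation_id = character(), position = integer(),
                  start = integer(), end = integer(), text = character(),
                  candidate_ids = list(), resolved_id = character())
  if (nrow(sentences) == 0 || nrow(dictionary) == 0) return(empty)
  if (expand) {
    sentences <- expand_sentence_abbreviations(sentences)
    sentences$text <- sentences$text_expanded
  }
  surfaces <- dictionary %>%
    group_by(.data$surface) %>%
    summarise(ids = list(sort(unique(.data$gene_id))), .groups = "drop") %>%
    arrange(dplyr::desc(nchar(.data$surface)), .data$surface)
  surf <- surfaces$surface
  surf_lower <- tolower(surf)
  case_sensitive <- surf %in% homonyms
  ids <- surfaces$ids
  rows <- purrr::pmap(
    list(sentences$citation_id, sentences$position, sentences$text),
    function(cid, pos, text) {
      hits <- match_one_sentence(text, surf, surf_lower, case_sensitive)
      if (nrow(hits) == 0) return(NULL)
      tibble(citation_id = cid, position = pos,
             start = hits$start, end = hits$end,
             text = substring(text, hits$start + 1L, hits$end),
             candidate_ids = ids[hits$entry],
             resolved_id = NA_character_)
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

# Greedy scan over token starts; at each start take the longest dictionary
# surface that matches there and ends at a token boundary, then jump past
# it. `surf` is ordered longest-first.
match_one_sentence <- function(text, surf, surf_lower, case_sensitive) {
  spans <- token_spans(text)
  out_start <- integer(0); out_end <- integer(0); out_entry <- integer(0)
  if (nrow(spans) == 0) {
    return(tibble(start = out_start, end = out_end, entry = out_entry))
  }
  text_lower <- tolower(text)
  starts <- spans[, 1]            # 0-based token starts
  ends <- spans[, 2]              # 0-based half-open token ends
  n <- nchar(text)
  i <- 1L
  while (i <= length(starts)) {
    s0 <- starts[i]
    hit <- 0L
    for (k in seq_along(surf)) {
      len <- nchar(surf[k])
      e0 <- s0 + len
      if (e0 > n) next
      # must end at a token boundary (end of a token run)
      if (!e0 %in% ends) next
      seg <- substr(if (case_sensitive[k]) text else text_lower,
                    s0 + 1L, e0)
      target <- if (case_sensitive[k]) surf[k] else surf_lower[k]
      if (seg == target) { hit <- k; break }
    }
    if (hit > 0L) {
      e0 <- s0 + nchar(surf[hit])
      out_start <- c(out_start, s0); out_end <- c(out_end, e0)
      out_entry <- c(out_entry, hit)
      i <- which(starts >= e0)[1] %||% (length(starts) + 1L)
      if (is.na(i)) i <- length(starts) + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble(start = out_start, end = out_end, entry = out_entry)
}

#' Resolve mentions by officialness
#'
#' Picks, for each mention, the candidate whose dictionary route is most
#' official: official symbol over official name over synonym. Remaining
#' ties break deterministically on the smallest gene identifier (numeric
#' order when every candidate id parses as a number, lexicographic
#' otherwise).
#'
#' @param mentions Mention tibble from [match_mentions()].
#' @param dictionary Dictionary tibble.
#' @return `mentions` with `resolved_id` filled.
#' @export
disambiguate_official <- function(mentions, dictionary) {
  if (nrow(mentions) == 0) return(mentions)
  key <- dictionary %>% select("surface", "gene_id", "rank")
  mentions$resolved_id <- purrr::map2_chr(
    mentions$text, mentions$candidate_ids,
    function(txt, cands) pick_official(txt, cands, key))
  mentions
}

pick_official <- function(txt, cands, key) {
  if (length(cands) == 1) return(cands[[1]])
  sub <- key[tolower(key$surface) == tolower(txt) &
               key$gene_id %in% cands, ]
  ranks <- if (nrow(sub) > 0) {
    setNames(sub$rank, sub$gene_id)[cands]
  } else {
    setNames(rep(RANK_SYNONYM, length(cands)), cands)
  }
  ranks[is.na(ranks)] <- RANK_SYNONYM
  best <- cands[ranks == min(ranks)]
  sort_gene_ids(best)[1]
}

sort_gene_ids <- function(ids) {
  nums <- suppressWarnings(as.numeric(ids))
  if (!anyNA(nums)) ids[order(nums)] else sort(ids)
}

#' Build per-gene term profiles
#'
#' For each gene, a weighted term vector over the lowercased,
#' stop-word-filtered tokens of its associated texts, weighted by term
#' frequency times inverse document frequency (idf = log(N/df) across
#' genes). Profiles drive context disambiguation of ambiguous mentions.
#'
#' @param texts A tibble with columns `gene_id`, `text` (one or more rows
#'   per gene).
#' @param stopwords Stop-word list.
#' @return A profile tibble: `gene_id`, `term`, `weight`.
#' @export
build_profiles <- function(texts, stopwords = default_stopwords()) {
  stopifnot(all(c("gene_id", "text") %in% names(texts)))
  counts <- texts %>%
    group_by(.data$gene_id) %>%
    summarise(text = paste(.data$text, collapse = " "), .groups = "drop") %>%
    mutate(term = tokenize(.data$text)) %>%
    select("gene_id", "term") %>%
    tidyr::unnest("term") %>%
    filter(!.data$term %in% stopwords) %>%
    count(.data$gene_id, .data$term, name = "tf")
  empty <- setdiff(unique(texts$gene_id), unique(counts$gene_id))
  if (length(empty) > 0) {
    abort(paste0("build_profiles(): only stop-word text for gene(s): ",
                 paste(empty, collapse = ", ")))
  }
  n_genes <- dplyr::n_distinct(counts$gene_id)
  counts %>%
    group_by(.data$term) %>%
    mutate(idf = log(n_genes / dplyr::n_distinct(.data$gene_id))) %>%
    ungroup() %>%
    mutate(weight = .data$tf * .data$idf) %>%
    select("gene_id", "term", "weight")
}

#' Resolve mentions by context-profile similarity
#'
#' For each ambiguous mention, the tokens of its sentence (plus `window`
#' neighboring sentences on each side) form a context profile that is
#' compared to each candidate gene's profile by cosine similarity; the
#' closest candidate wins. Ties — including an all-zero similarity — and
#' candidates lacking a profile fall back to officialness ranking.
#'
#' @param mentions Mention tibble from [match_mentions()].
#' @param sentences Sentence tibble covering the mentions' citations.
#' @param profiles Profile tibble from [build_profiles()].
#' @param dictionary Dictionary tibble (for the officialness fallback).
#' @param window Number of neighboring sentences on each side (default 0:
#'   the mention's sentence only).
#' @param stopwords Stop-word list used for context tokens.
#' @return `mentions` with `resolved_id` filled.
#' @export
disambiguate_profile <- function(mentions, sentences, profiles, dictionary,
                                 window = 0, stopwords = default_stopwords()) {
  if (nrow(mentions) == 0) return(mentions)
  prof_split <- split(profiles, profiles$gene_id)
  key <- dictionary %>% select("surface", "gene_id", "rank")
  mentions$resolved_id <- purrr::pmap_chr(
    list(mentions$citation_id, mentions$position, mentions$text,
         mentions$candidate_ids),
    function(cid, pos, txt, cands) {
      if (length(cands) == 1) return(cands[[1]])
      if (!all(cands %in% names(prof_split))) {
        inform(sprintf(
          "mention '%s' (%s:%d): candidate without profile; using officialness",
          txt, cid, pos))
        return(pick_official(txt, cands, key))
      }
      ctx <- sentences$text[sentences$citation_id == cid &
                              abs(sentences$position - pos) <= window]
      terms <- unlist(tokenize(paste(ctx, collapse = " ")))
      terms <- terms[!terms %in% stopwords]
      ctx_tf <- table(terms)
      sims <- vapply(cands, function(g) {
        p <- prof_split[[g]]
        shared <- intersect(names(ctx_tf), p$term)
        if (length(shared) == 0) return(0)
        w <- setNames(p$weight, p$term)
        num <- sum(as.numeric(ctx_tf[shared]) * w[shared])
        den <- sqrt(sum(as.numeric(ctx_tf)^2)) * sqrt(sum(p$weight^2))
        if (den == 0) 0 else num / den
      }, numeric(1))
      top <- cands[sims == max(sims)]
      if (length(top) > 1 || max(sims) == 0) {
        return(pick_official(txt, cands, key))
      }
      top[1]
    })
  mentions
}

#' Write mentions to a tab-separated file
#' @param mentions Mention tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  out <- mentions %>%
    mutate(candidate_ids = purrr::map_chr(.data$candidate_ids,
                                          paste, collapse = "|"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
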