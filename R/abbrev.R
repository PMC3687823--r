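# Parenthetical abbreviation resolution (Schwartz-Hearst character
# alignment). Locally defined short forms are replaced by their long form in
# the remainder of the text, which removes a large class of dictionary
# false positives before gene-mention matching.

# A candidate short form: 2-10 characters, at most two words, at least one
# letter, first character alphanumeric.
is_valid_short_form <- function(sf) {
  nc <- nchar(sf)
  if (nc < 2 || nc > 10) return(FALSE)
  if (length(strsplit(trimws(sf), "\\s+")[[1]]) > 2) return(FALSE)
  if (!grepl("[A-Za-z]", sf)) return(FALSE)
  grepl("^[A-Za-z0-9]", sf)
}

# Character-alignment rule: scan the short form right-to-left; each
# alphanumeric character must match (case-insensitively) a character of the
# long form, also scanned right-to-left; the first character of the short
# form must match at the start of a word. Returns the matched long form or
# NA.
find_best_long_form <- function(short_form, long_form) {
  s <- strsplit(short_form, "")[[1]]
  l <- strsplit(long_form, "")[[1]]
  s_index <- length(s)
  l_index <- length(l)
  while (s_index >= 1) {
    curr <- tolower(s[s_index])
    if (!grepl("[a-z0-9]", curr)) {
      s_index <- s_index - 1
      next
    }
    while (l_index >= 1 &&
           (tolower(l[l_index]) != curr ||
            (s_index == 1 && l_index > 1 &&
             grepl("[A-Za-z0-9]", l[l_index - 1])))) {
      l_index <- l_index - 1
    }
    if (l_index < 1) return(NA_character_)
    l_index <- l_index - 1
    s_index <- s_index - 1
  }
  # expand left to the start of the word containing the first matched char
  prefix <- substr(long_form, 1, l_index)
  word_start <- regexpr("[^ ]*$", prefix)
  start <- if (word_start > 0) word_start else l_index + 1
  trimws(substring(long_form, start))
}

#' Resolve and expand parenthetical abbreviations
#'
#' Finds short forms defined in parentheses ("vascular endothelial growth
#' factor (VEGF)"), aligns each against the preceding words with the
#' Schwartz-Hearst character-alignment rule, and replaces later standalone
#' occurrences of the short form in the remainder of the text with the long
#' form. Parentheticals that do not qualify as short forms (e.g. "(n = 25)")
#' or that cannot be aligned are left untouched.
#'
#' @param text A single text string (typically a whole title + abstract, so
#'   definitions carry across sentences).
#' @return A list with `text` (the expanded text) and `map` (a tibble with
#'   columns `short`, `long`; zero rows when nothing was resolved).
#' @export
#' @examples
#' expand_abbreviations(
#'   "Vascular endothelial growth factor (VEGF) was assayed. VEGF rose.")
expand_abbreviations <- function(text) {
  stopifnot(length(text) == 1)
  map <- tibble(short = character(), long = character())
  if (is.na(text) || !nzchar(text)) return(list(text = text, map = map))
  search_from <- 1L
  repeat {
    rest <- substring(text, search_from)
    m <- stringr::str_locate(rest, "\\(([^()]+)\\)")
    if (any(is.na(m))) break
    open <- search_from + m[1, 1] - 1L
    close <- search_from + m[1, 2] - 1L
    sf <- substr(text, open + 1L, close - 1L)
    if (is_valid_short_form(sf) && !sf %in% map$short) {
      before <- trimws(substr(text, 1, open - 1L))
      # candidate long form: the trailing min(|sf| + 5, 2|sf|) words of the
      # current sentence
      before <- stringr::str_extract(before, "[^.!?]*$")
      words <- strsplit(trimws(before), "\\s+")[[1]]
      max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
      cand <- paste(tail(words, max_words), collapse = " ")
      long <- if (nzchar(cand)) find_best_long_form(sf, cand) else NA_character_
      if (!is.na(long) && nzchar(long) && tolower(long) != tolower(sf)) {
        map <- dplyr::bind_rows(map, tibble(short = sf, long = long))
        head_part <- substr(text, 1, close)
        tail_part <- substring(text, close + 1L)
        pattern <- paste0("(?<![A-Za-z0-9])",
                          stringr::str_escape(sf),
                          "(?![A-Za-z0-9])")
        tail_part <- stringr::str_replace_all(
          tail_part, stringr::regex(pattern), long)
        text <- paste0(head_part, tail_part)
        close <- nchar(head_part)
      }
    }
    search_from <- close + 1L
    if (search_from > nchar(text)) break
  }
  list(text = text, map = map)
}

#' Expand abbreviations across the sentences of each citation
#'
#' Applies [expand_abbreviations()] citation-wise, so a short form defined
#' in an early sentence is expanded in all later sentences of the same
#' citation. Adds a `text_expanded` column.
#'
#' @param sentences Sentence tibble from [segment_sentences()].
#' @return `sentences` with a `text_expanded` column.
#' @export
expand_sentence_abbreviations <- function(sentences) {
  sentences %>%
    group_by(.data$citation_id) %>%
    mutate(text_expanded = {
      joined <- paste(.data$text, collapse = "\n")
      out <- expand_abbreviations(gsub("\n", " \n ", joined))$text
      parts <- strsplit(gsub(" \n ", "\n", out, fixed = TRUE),
                        "\n", fixed = TRUE)[[1]]
      if (length(parts) == length(.data$text)) parts else .data$text
    }) %>%
    ungroup()
}
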