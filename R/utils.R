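# Shared low-level helpers: tokenization, packaged resources, seeds.

#' Tokenize text into word tokens
#'
#' Splits on transitions between word characters (letters, digits, underscore)
#' and everything else. Used for bag-of-words features, Gene Ontology term
#' density and gene-name profile construction.
#'
#' @param x Character vector of texts.
#' @param lowercase Lowercase tokens before returning?
#' @return A list of character vectors, one per input text.
#' @export
#' @examples
#' tokenize("The gene WAS expressed.")
tokenize <- function(x, lowercase = TRUE) {
  if (lowercase) x <- tolower(x)
  toks <- stringr::str_extract_all(x, "[A-Za-z0-9_]+")
  toks
}

# Token boundary positions for mention matching: start/end (0-based half-open)
# of every maximal word-character run in `text`.
token_spans <- function(text) {
  m <- stringr::str_locate_all(text, "[A-Za-z0-9_]+")[[1]]
  if (nrow(m) == 0) return(matrix(integer(0), ncol = 2))
  cbind(m[, 1] - 1L, m[, 2])  # 0-based half-open
}

#' English stop-word list shipped with the package
#'
#' A packaged snapshot of a standard English stop-word list, used by the
#' bag-of-words text features and the gene-profile builder.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "generifsel")
  readr::read_lines(path, progress = FALSE)
}

#' Gene-name homonym list shipped with the package
#'
#' Gene symbols that double as common English words (e.g. "WAS", "SET",
#' "IMPACT"). Dictionary matching treats these case-sensitively to avoid
#' false positives; the list is an editable text resource.
#'
#' @return Character vector of surface forms matched case-sensitively.
#' @export
default_homonyms <- function() {
  path <- system.file("extdata", "gene_homonyms.txt", package = "generifsel")
  readr::read_lines(path, progress = FALSE)
}

#' Non-human organism MeSH headings shipped with the package
#'
#' Used by the citation filters to drop citations denoting species other
#' than humans (a heading from this list present and "Humans" absent).
#'
#' @return Character vector of MeSH headings.
#' @export
default_nonhuman_mesh <- function() {
  path <- system.file("extdata", "nonhuman_mesh.txt", package = "generifsel")
  readr::read_lines(path, progress = FALSE)
}

#' Structured-abstract heading normalization map
#'
#' Maps raw section headings (BACKGROUND, AIMS, CONCLUSION, ...) to the five
#' canonical discourse labels. Shipped as an editable two-column
#' tab-separated resource; `read_heading_map()` reads any file in the same
#' layout.
#'
#' @param path Path to a two-column tab-separated file (heading, label).
#' @return A named character vector: names are uppercase headings, values
#'   canonical labels.
#' @export
default_heading_map <- function() {
  read_heading_map(system.file("extdata", "heading_map.tsv",
                               package = "generifsel"))
}

#' @rdname default_heading_map
#' @export
read_heading_map <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("heading", "label"),
                         col_types = "cc", progress = FALSE)
  bad <- setdiff(unique(tab$label), discourse_levels())
  if (length(bad) > 0) {
    abort(paste0("heading map contains non-canonical labels: ",
                 paste(bad, collapse = ", ")))
  }
  setNames(tab$label, toupper(tab$heading))
}

#' Demonstration Gene Ontology term table
#'
#' A small table of Gene Ontology process/function term strings used by the
#' GO-density feature in examples and tests. Any two-column (id, term)
#' tab-separated file in the same layout can be substituted.
#'
#' @return A tibble with columns `go_id`, `term`.
#' @export
default_go_terms <- function() {
  path <- system.file("extdata", "go_terms_demo.tsv", package = "generifsel")
  readr::read_tsv(path, col_names = c("go_id", "term"), col_types = "cc",
                  progress = FALSE)
}

# Canonical discourse label vocabulary (prediction space).
discourse_levels <- function() {
  c("Background", "Objective", "Methods", "Results", "Conclusions",
    "Title", "Unknown")
}

# Trainable (abstract-sentence) labels, in tie-break priority order.
discourse_core_levels <- function() {
  c("Background", "Objective", "Methods", "Results", "Conclusions")
}

# The 6-way gold annotation vocabulary uses "Purpose"; the one-hot encoding
# shares the canonical vocabulary, so Purpose folds into Objective.
canonicalize_discourse <- function(x) {
  ifelse(x == "Purpose", "Objective", x)
}

# run code under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- rlang::`%||%`
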