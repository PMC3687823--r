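# Per-sentence feature extraction and matrix assembly. Feature blocks:
#   pos   sentence number from the start of the citation (title = 1)
#   posf  total sentence count minus sentence number (last sentence = 0)
#   text  bag-of-words counts (unigrams or bigrams, lowercased, stop words
#         removed)
#   gene  mention count, distinct resolved genes, binary presence
#   dis   one-hot discourse label from the boosted ensemble (or gold)
#   disg  one-hot discourse label from the sequence labeler
#   go    Gene Ontology term density

#' Feature configuration
#'
#' @param feature_set Non-empty subset of
#'   `c("pos","posf","text","gene","dis","disg","go")`; `dis` and `disg`
#'   are mutually exclusive in one configuration.
#' @param text_ngram 1 (unigrams) or 2 (bigrams).
#' @param stopwords Stop-word list for the text block.
#' @param discourse_source Where the `dis` block's labels come from:
#'   predictions of the ensemble or sequence labeler, or gold annotations
#'   (6-way gold labels fold Purpose into Objective).
#' @return A `feature_config` list.
#' @export
feature_config <- function(feature_set = c("posf", "dis"),
                           text_ngram = 1,
                           stopwords = default_stopwords(),
                           discourse_source = c("predicted-ensemble",
                                                "predicted-sequence",
                                                "gold")) {
  discourse_source <- match.arg(discourse_source)
  known <- c("pos", "posf", "text", "gene", "dis", "disg", "go")
  if (length(feature_set) == 0) {
    abort("feature_config(): feature_set must be non-empty")
  }
  bad <- setdiff(feature_set, known)
  if (length(bad) > 0) {
    abort(paste0("feature_config(): unknown feature(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (all(c("dis", "disg") %in% feature_set)) {
    abort("feature_config(): 'dis' and 'disg' are mutually exclusive")
  }
  if (!text_ngram %in% c(1, 2)) {
    abort("feature_config(): text_ngram must be 1 or 2")
  }
  structure(list(feature_set = feature_set, text_ngram = text_ngram,
                 stopwords = stopwords, discourse_source = discourse_source),
            class = "feature_config")
}

#' Sentence position features
#'
#' `pos` is the sentence number from the start of the citation (the title
#' is 1); `posf` is the total number of sentences minus the sentence
#' number, so the last sentence scores 0 and `pos + posf = N` on every row.
#'
#' @param sentences Sentence tibble from [segment_sentences()].
#' @return `sentences` with numeric columns `pos` and `posf` appended.
#' @export
extract_position <- function(sentences) {
  sentences %>%
    group_by(.data$citation_id) %>%
    mutate(pos = as.numeric(.data$position),
           posf = max(.data$position) - .data$position) %>%
    ungroup()
}

#' Bag-of-words term counts per sentence
#'
#' Tokens are lowercased and stop words removed; n-grams are formed from
#' consecutive surviving tokens. A sentence of only stop words yields no
#' rows.
#'
#' @param sentences Sentence tibble.
#' @param ngram 1 or 2.
#' @param stopwords Stop-word list.
#' @return Long tibble: `citation_id`, `position`, `term`, `n`.
#' @export
extract_text_counts <- function(sentences, ngram = 1,
                                stopwords = default_stopwords()) {
  toks <- tokenize(sentences$text)
  toks <- purrr::map(toks, function(t) t[!t %in% stopwords])
  if (ngram == 2) {
    toks <- purrr::map(toks, function(t) {
      if (length(t) < 2) return(character(0))
      paste(t[-length(t)], t[-1], sep = "_")
    })
  }
  sentences %>%
    select("citation_id", "position") %>%
    mutate(term = toks) %>%
    tidyr::unnest("term") %>%
    count(.data$citation_id, .data$position, .data$term)
}

#' Gene-mention features per sentence
#'
#' Three numeric columns from the lexicon module's mentions: total mention
#' count, number of distinct resolved gene identifiers, and binary
#' presence.
#'
#' @param sentences Sentence tibble.
#' @param mentions Mention tibble from [match_mentions()] (after
#'   disambiguation if resolved counts should distinguish genes; unresolved
#'   mentions count each distinct surface's candidate set as one).
#' @return `sentences` keys with `gene_mentions`, `gene_distinct`,
#'   `gene_present`.
#' @export
extract_gene_features <- function(sentences, mentions) {
  agg <- mentions %>%
    mutate(gid = ifelse(is.na(.data$resolved_id),
                        purrr::map_chr(.data$candidate_ids, paste,
                                       collapse = "|"),
                        .data$resolved_id)) %>%
    group_by(.data$citation_id, .data$position) %>%
    summarise(gene_mentions = dplyr::n(),
              gene_distinct = dplyr::n_distinct(.data$gid),
              .groups = "drop")
  sentences %>%
    select("citation_id", "position") %>%
    left_join(agg, by = c("citation_id", "position")) %>%
    mutate(gene_mentions = dplyr::coalesce(.data$gene_mentions, 0L),
           gene_distinct = dplyr::coalesce(.data$gene_distinct, 0L),
           gene_present = as.integer(.data$gene_mentions > 0))
}

#' One-hot discourse features
#'
#' Exactly one of the seven columns (Background, Objective, Methods,
#' Results, Conclusions, Title, Unknown) is 1 per sentence.
#'
#' @param sentences Sentence tibble.
#' @param discourse Tibble `citation_id`, `position`, `label` (predictions
#'   from [predict_discourse()] or gold labels; the gold "Purpose" maps to
#'   Objective).
#' @param prefix Column prefix, `"dis"` or `"disg"`.
#' @return `sentences` keys with the one-hot columns appended.
#' @export
extract_discourse_features <- function(sentences, discourse,
                                       prefix = "dis") {
  keys <- sentences %>% select("citation_id", "position")
  joined <- keys %>%
    left_join(discourse %>% select("citation_id", "position", "label"),
              by = c("citation_id", "position"))
  if (anyNA(joined$label)) {
    miss <- joined[is.na(joined$label), ][1, ]
    abort(sprintf("extract_discourse_features(): missing discourse label for %s position %d",
                  miss$citation_id, miss$position))
  }
  lab <- canonicalize_discourse(joined$label)
  bad <- setdiff(unique(lab), discourse_levels())
  if (length(bad) > 0) {
    abort(paste0("extract_discourse_features(): unknown label(s): ",
                 paste(bad, collapse = ", ")))
  }
  for (lv in discourse_levels()) {
    keys[[paste0(prefix, "_", lv)]] <- as.numeric(lab == lv)
  }
  keys
}

#' Gene Ontology term density of a sentence
#'
#' A self-contained stand-in for external GO-evidence scorers: the sentence
#' is tokenized (lowercased, stop words kept, since GO terms contain
#' function words), maximal non-overlapping GO-term token matches are found
#' greedily longest-first, and the density is the sum of squared matched
#' token counts divided by the sentence token count. Zero when no GO term
#' matches; invariant under self-concatenation of the sentence. The scale
#' is not comparable to external GO-evidence scores.
#'
#' @param sentences Sentence tibble.
#' @param go_terms Tibble with columns `go_id`, `term` (see
#'   [default_go_terms()]).
#' @return `sentences` keys with numeric column `go_density`.
#' @export
extract_go_density <- function(sentences, go_terms = default_go_terms()) {
  if (is.null(go_terms) || nrow(go_terms) == 0) {
    abort("extract_go_density(): empty GO term table")
  }
  term_tokens <- tokenize(go_terms$term)
  term_tokens <- term_tokens[lengths(term_tokens) > 0]
  ord <- order(-lengths(term_tokens))
  term_tokens <- term_tokens[ord]
  dens <- vapply(tokenize(sentences$text), function(toks) {
    n <- length(toks)
    if (n == 0) return(0)
    used <- rep(FALSE, n)
    score <- 0
    for (tt in term_tokens) {
      k <- length(tt)
      if (k > n) next
      i <- 1
      while (i <= n - k + 1) {
        if (!any(used[i:(i + k - 1)]) &&
            all(toks[i:(i + k - 1)] == tt)) {
          used[i:(i + k - 1)] <- TRUE
          score <- score + k^2
          i <- i + k
        } else {
          i <- i + 1
        }
      }
    }
    score / n
  }, numeric(1))
  sentences %>%
    select("citation_id", "position") %>%
    mutate(go_density = dens)
}

#' Assemble a feature matrix
#'
#' Builds the per-sentence feature matrix for a named feature-set
#' combination (e.g. `posf + dis + go`). Columns are the union of the
#' requested feature blocks in a deterministic order; rows are keyed by
#' `(citation_id, position)`; the gold GeneRIF flag is attached as a
#' `gold_generif` label column when present. A requested feature whose
#' dependency was not supplied raises an error naming the feature.
#'
#' @param sentences Sentence tibble from [segment_sentences()].
#' @param config A [feature_config()] (or a character vector shorthand for
#'   its `feature_set`).
#' @param mentions Mention tibble (required for `"gene"`).
#' @param discourse Discourse label tibble (required for `"dis"`/`"disg"`
#'   unless `discourse_source = "gold"`, which reads `gold_discourse` from
#'   `sentences`).
#' @param go_terms GO term table (required for `"go"`; defaults to the
#'   packaged demonstration table).
#' @return A wide tibble: `citation_id`, `position`, feature columns, and
#'   `gold_generif` when available. All feature values are finite; no
#'   missing values.
#' @export
assemble_features <- function(sentences, config = feature_config(),
                              mentions = NULL, discourse = NULL,
                              go_terms = NULL) {
  if (is.character(config)) config <- feature_config(feature_set = config)
  stopifnot(inherits(config, "feature_config"))
  fs <- config$feature_set
  out <- extract_position(sentences) %>%
    select("citation_id", "position", "pos", "posf")
  if (!"pos" %in% fs) out$pos <- NULL
  if (!"posf" %in% fs) out$posf <- NULL
  if ("gene" %in% fs) {
    if (is.null(mentions)) {
      abort("assemble_features(): feature 'gene' requested but no mentions supplied")
    }
    out <- out %>% left_join(extract_gene_features(sentences, mentions),
                             by = c("citation_id", "position"))
  }
  for (dfeat in c("dis", "disg")) {
    if (dfeat %in% fs) {
      dsrc <- discourse
      if (config$discourse_source == "gold") {
        if (!"gold_discourse" %in% names(sentences) ||
            anyNA(sentences$gold_discourse)) {
          abort(sprintf("assemble_features(): feature '%s' with gold source needs complete gold_discourse",
                        dfeat))
        }
        dsrc <- sentences %>%
          select("citation_id", "position") %>%
          mutate(label = sentences$gold_discourse)
      }
      if (is.null(dsrc)) {
        abort(sprintf("assemble_features(): feature '%s' requested but no discourse labels supplied",
                      dfeat))
      }
      out <- out %>%
        left_join(extract_discourse_features(sentences, dsrc,
                                             prefix = dfeat),
                  by = c("citation_id", "position"))
    }
  }
  if ("go" %in% fs) {
    go_terms <- go_terms %||% default_go_terms()
    out <- out %>% left_join(extract_go_density(sentences, go_terms),
                             by = c("citation_id", "position"))
  }
  if ("text" %in% fs) {
    counts <- extract_text_counts(sentences, ngram = config$text_ngram,
                                  stopwords = config$stopwords)
    wide <- counts %>%
      mutate(term = paste0("text_", .data$term)) %>%
      tidyr::pivot_wider(names_from = "term", values_from = "n",
                         values_fill = 0)
    wide <- wide[, c("citation_id", "position",
                     sort(setdiff(names(wide),
                                  c("citation_id", "position"))))]
    out <- out %>% left_join(wide, by = c("citation_id", "position"))
    out[is.na(out)] <- 0
  }
  if ("gold_generif" %in% names(sentences) &&
      !all(is.na(sentences$gold_generif))) {
    out <- out %>%
      left_join(sentences %>% select("citation_id", "position",
                                     "gold_generif"),
                by = c("citation_id", "position"))
  }
  stopifnot(!anyNA(out %>% select(-dplyr::any_of("gold_generif"))))
  out
}

#' Write a feature matrix to a tab-separated file
#' @param matrix Feature tibble from [assemble_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}
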