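# Independent oracles and in-code fixtures shared across the suite.

# ---- hand-rolled Gaussian Bayes oracle (independent of e1071) --------------
# Posterior over classes for one new row, computed directly from the
# Bayes rule with per-class feature means/sds (n-1 denominator) and
# empirical class priors.
nb_oracle_posterior <- function(x_train, y_train, x_new) {
  classes <- levels(y_train)
  priors <- table(y_train) / length(y_train)
  joint <- vapply(classes, function(cl) {
    xs <- x_train[y_train == cl, , drop = FALSE]
    dens <- 1
    for (j in seq_along(x_new)) {
      dens <- dens * stats::dnorm(x_new[[j]], mean(xs[[j]]),
                                  stats::sd(xs[[j]]))
    }
    as.numeric(priors[[cl]]) * dens
  }, numeric(1))
  joint / sum(joint)
}

# ---- exhaustive leftmost-longest matching oracle ---------------------------
# Enumerates every candidate dictionary match in a text, then every maximal
# non-overlapping cover, and picks the cover maximal under the preference
# order (earlier first match, then longer first match, position by
# position). Independent of the greedy scanner.
oracle_all_matches <- function(text, surfaces) {
  spans <- stringr::str_locate_all(text, "[A-Za-z0-9_]+")[[1]]
  if (nrow(spans) == 0) return(data.frame(start = integer(), end = integer()))
  starts0 <- spans[, 1] - 1L
  ends0 <- spans[, 2]
  text_lower <- tolower(text)
  out <- list()
  for (s0 in starts0) {
    for (surf in surfaces) {
      e0 <- s0 + nchar(surf)
      if (e0 > nchar(text) || !e0 %in% ends0) next
      if (substr(text_lower, s0 + 1, e0) == tolower(surf)) {
        out[[length(out) + 1]] <- data.frame(start = s0, end = e0)
      }
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

oracle_leftmost_longest <- function(text, surfaces) {
  cands <- oracle_all_matches(text, surfaces)
  if (nrow(cands) == 0) return(cands)
  cands <- cands[order(cands$start, -cands$end), , drop = FALSE]
  # Enumerate every maximal non-overlapping cover. Any maximal cover must
  # contain a candidate overlapping the leftmost remaining candidate
  # (otherwise that candidate could be added); branch on which one.
  enumerate <- function(idx) {
    if (length(idx) == 0) return(list(integer(0)))
    c0 <- idx[which.min(cands$start[idx])]
    overlaps_c0 <- idx[cands$start[idx] < cands$end[c0] &
                         cands$end[idx] > cands$start[c0]]
    out <- list()
    for (c in overlaps_c0) {
      rest <- idx[cands$start[idx] >= cands$end[c] |
                    cands$end[idx] <= cands$start[c]]
      for (tail_cover in enumerate(rest)) {
        out[[length(out) + 1]] <- c(c, tail_cover)
      }
    }
    out
  }
  covers <- enumerate(seq_len(nrow(cands)))
  covers <- lapply(covers, function(cv) cv[order(cands$start[cv])])
  score_better <- function(a, b) {
    # TRUE if cover a is preferred over b
    sa <- cands[a, , drop = FALSE]; sb <- cands[b, , drop = FALSE]
    for (k in seq_len(min(nrow(sa), nrow(sb)))) {
      if (sa$start[k] != sb$start[k]) return(sa$start[k] < sb$start[k])
      la <- sa$end[k] - sa$start[k]; lb <- sb$end[k] - sb$start[k]
      if (la != lb) return(la > lb)
    }
    nrow(sa) >= nrow(sb)
  }
  best <- covers[[1]]
  for (cv in covers[-1]) if (!score_better(best, cv)) best <- cv
  cands[best, , drop = FALSE]
}

# random matching instance: small dictionary with overlapping multi-token
# surfaces plus a token sentence
random_match_instance <- function() {
  alphabet <- c("alpha", "beta", "gamma", "delta", "kinase", "p1", "p12",
                "rec", "tor", "x")
  n_entries <- sample(3:20, 1)
  surfaces <- unique(vapply(seq_len(n_entries), function(i) {
    paste(sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = " ")
  }, character(1)))
  records <- tibble::tibble(
    gene_id = as.character(seq_along(surfaces)),
    official_symbol = NA_character_, official_name = NA_character_,
    synonyms = as.list(surfaces))
  dict <- build_dictionary(records, banned_suffixes = character(0))
  sentence <- paste(sample(alphabet, sample(5:30, 1), replace = TRUE),
                    collapse = " ")
  list(dict = dict, sentence = sentence, surfaces = unique(dict$surface))
}

# greedy matcher vs oracle on one instance
greedy_equals_oracle <- function(inst) {
  sent <- tibble::tibble(citation_id = "c1", position = 1L,
                         text = inst$sentence)
  got <- match_mentions(sent, inst$dict, homonyms = character(0),
                        expand = FALSE)
  want <- oracle_leftmost_longest(inst$sentence, inst$surfaces)
  identical(as.integer(got$start), as.integer(want$start)) &&
    identical(as.integer(got$end), as.integer(want$end))
}

# ---- tiny corpora built in code --------------------------------------------
fixture_lines <- function() {
  c(paste0("id=C1\tjournal=J Test\tpubtypes=Journal Article\t",
           "mesh=Humans|Alleles\ttitle=TP53 drives repair\t",
           "abstract=We measured levels. TP53 rose sharply.\t",
           "gold_generif=1,3\tgold_discourse=1:Title,2:Methods,3:Results"),
    paste0("id=C2\ttitle=A title only record"),
    paste0("id=C3\ttitle=Structured record\t",
           "abstract=Known context here. We saw a rise. It matters now.\t",
           "sections=BACKGROUND:2-2;RESULTS:3-4"))
}

write_fixture <- function(lines = fixture_lines()) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

pubmed_xml_string <- function() {
  paste0(
    '<?xml version="1.0"?>\n<PubmedArticleSet>\n',
    '<PubmedArticle><MedlineCitation><PMID>11111</PMID>',
    '<Article><Journal><Title>J Hum Genet</Title></Journal>',
    '<ArticleTitle>BRCA1 function in repair</ArticleTitle>',
    '<Abstract>',
    '<AbstractText Label="BACKGROUND">Context is known.</AbstractText>',
    '<AbstractText Label="RESULTS">BRCA1 rose. Levels fell.</AbstractText>',
    '</Abstract>',
    '<PublicationTypeList><PublicationType>Journal Article</PublicationType>',
    '</PublicationTypeList></Article>',
    '<MeshHeadingList><MeshHeading><DescriptorName>Humans</DescriptorName>',
    '</MeshHeading></MeshHeadingList>',
    '</MedlineCitation></PubmedArticle>\n',
    '</PubmedArticleSet>\n')
}

# a small labeled, separable feature table for selector tests
toy_selector_matrix <- function(n = 60, seed = 5) {
  withr::with_seed(seed, {
    pos <- rep(c(TRUE, FALSE), length.out = n)
    tibble::tibble(
      citation_id = sprintf("T%02d", seq_len(n)),
      position = rep(1:5, length.out = n),
      f1 = ifelse(pos, stats::rnorm(n, 3), stats::rnorm(n, -3)),
      f2 = stats::rnorm(n),
      gold_generif = pos)
  })
}
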