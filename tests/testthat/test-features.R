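mini_sentences <- function() {
  tibble::tibble(
    citation_id = rep(c("A", "B"), c(4, 3)),
    position = c(1:4, 1:3),
    text = c("Gene title", "The gene WAS expressed", "of the and",
             "regulation of apoptosis occurs",
             "Another title", "Methods were used", "We conclude function"),
    gold_generif = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    gold_discourse = c("Title", "Background", "Methods", "Results",
                       "Title", "Methods", "Purpose"),
    gold_claim = NA_character_, gold_subcategory = NA_character_)
}

test_that("pos and posf are the two positional features and sum to N", {
  f <- extract_position(mini_sentences())
  expect_equal(f$pos, c(1:4, 1:3))
  expect_equal(f$posf, c(3:0, 2:0))
  expect_true(all(f$pos + f$posf ==
                    c(rep(4, 4), rep(3, 3))))
  # property over a generated corpus
  corp <- generate_corpus(synth_config(seed = 13, n_train = 30, n_test = 10))
  fp <- extract_position(segment_sentences(corp$citations))
  n_per <- fp %>% dplyr::group_by(citation_id) %>%
    dplyr::mutate(N = max(position)) %>% dplyr::ungroup()
  expect_true(all(n_per$pos + n_per$posf == n_per$N))
})

test_that("text features lowercase, drop stop words, and form n-grams", {
  s <- mini_sentences()[2, ]
  uni <- extract_text_counts(s, ngram = 1, stopwords = c("the", "was"))
  expect_setequal(uni$term, c("gene", "expressed"))
  expect_true(all(uni$n == 1))
  bi <- extract_text_counts(s, ngram = 2, stopwords = c("the", "was"))
  expect_equal(bi$term, "gene_expressed")
  empty <- extract_text_counts(mini_sentences()[3, ], ngram = 1,
                               stopwords = c("of", "the", "and"))
  expect_equal(nrow(empty), 0)
})

test_that("gene features count mentions, distinct genes, and presence", {
  sents <- mini_sentences()
  mentions <- tibble::tibble(
    citation_id = c("A", "A", "A", "A", "A"),
    position = c(1L, 1L, 2L, 2L, 2L),
    start = 0L, end = 1L, text = "x",
    candidate_ids = list("g1", "g1", "g1", "g2", "g2"),
    resolved_id = c("g1", "g1", "g1", "g2", "g2"))
  g <- extract_gene_features(sents, mentions)
  expect_equal(g[g$citation_id == "A" & g$position == 1, ]$gene_mentions, 2L)
  expect_equal(g[g$citation_id == "A" & g$position == 1, ]$gene_distinct, 1L)
  expect_equal(g[g$citation_id == "A" & g$position == 1, ]$gene_present, 1L)
  expect_equal(g[g$citation_id == "A" & g$position == 2, ]$gene_mentions, 3L)
  expect_equal(g[g$citation_id == "A" & g$position == 2, ]$gene_distinct, 2L)
  none <- g[g$citation_id == "B", ]
  expect_true(all(none$gene_mentions == 0 & none$gene_present == 0))
})

test_that("discourse one-hot has exactly one hot column, Purpose folds to Objective", {
  sents <- mini_sentences()
  gold <- sents %>% dplyr::select(citation_id, position) %>%
    dplyr::mutate(label = sents$gold_discourse)
  oh <- extract_discourse_features(sents, gold)
  hot <- rowSums(oh[grep("^dis_", names(oh))])
  expect_true(all(hot == 1))
  expect_equal(oh$dis_Objective[7], 1)   # gold Purpose
  expect_equal(oh$dis_Title[c(1, 5)], c(1, 1))
  missing <- gold[-1, ]
  expect_error(extract_discourse_features(sents, missing), "missing")
})

test_that("GO density follows the squared-match-over-length form", {
  go <- tibble::tibble(go_id = c("GO:1", "GO:2"),
                       term = c("regulation of apoptosis", "kinase activity"))
  s <- tibble::tibble(citation_id = "A", position = 1L,
                      text = "regulation of apoptosis occurs")
  d <- extract_go_density(s, go)
  expect_equal(d$go_density, 9 / 4)  # 3 matched tokens squared over 4 tokens
  # zero when no GO tokens appear
  s0 <- tibble::tibble(citation_id = "A", position = 1L,
                       text = "unrelated words entirely")
  expect_equal(extract_go_density(s0, go)$go_density, 0)
  # invariant under self-concatenation
  s2 <- s
  s2$text <- paste(s$text, s$text)
  expect_equal(extract_go_density(s2, go)$go_density, d$go_density)
  # longer terms are matched before their components
  go2 <- tibble::tibble(go_id = c("a", "b"),
                        term = c("apoptosis", "regulation of apoptosis"))
  expect_equal(extract_go_density(s, go2)$go_density, 9 / 4)
  expect_error(extract_go_density(s, go[0, ]), "empty")
})

test_that("assembly builds the requested blocks with labels attached", {
  sents <- mini_sentences()
  m1 <- assemble_features(sents, "pos")
  expect_equal(dim(m1), c(7, 4))  # keys + pos + label
  expect_true("gold_generif" %in% names(m1))
  gold <- sents %>% dplyr::select(citation_id, position) %>%
    dplyr::mutate(label = sents$gold_discourse)
  m2 <- assemble_features(sents, c("posf", "dis", "go"), discourse = gold)
  expect_setequal(
    setdiff(names(m2), c("citation_id", "position", "gold_generif")),
    c("posf", paste0("dis_", c("Background", "Objective", "Methods",
                               "Results", "Conclusions", "Title",
                               "Unknown")), "go_density"))
  cfg_gold <- feature_config(c("posf", "dis"), discourse_source = "gold")
  m3 <- assemble_features(sents, cfg_gold)
  expect_equal(m3$dis_Objective[7], 1)
  # text block widens term counts
  m4 <- assemble_features(sents, c("pos", "text"))
  expect_true(any(grepl("^text_", names(m4))))
  expect_false(anyNA(m4))
})

test_that("invalid or incomplete feature requests are rejected by name", {
  sents <- mini_sentences()
  expect_error(feature_config(c("dis", "disg")), "mutually exclusive")
  expect_error(feature_config(character(0)), "non-empty")
  expect_error(feature_config("pos", text_ngram = 3), "1 or 2")
  expect_error(assemble_features(sents, "gene"), "gene")
  expect_error(assemble_features(sents, "dis"), "dis")
})

test_that("feature extraction is label-blind", {
  sents <- mini_sentences()
  gold <- sents %>% dplyr::select(citation_id, position) %>%
    dplyr::mutate(label = sents$gold_discourse)
  base <- assemble_features(sents, c("pos", "posf", "go", "text"),
                            discourse = gold)
  shuffled <- sents
  withr::with_seed(4, {
    shuffled$gold_generif <- sample(shuffled$gold_generif)
  })
  perm <- assemble_features(shuffled, c("pos", "posf", "go", "text"),
                            discourse = gold)
  expect_identical(base %>% dplyr::select(-gold_generif),
                   perm %>% dplyr::select(-gold_generif))
})
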