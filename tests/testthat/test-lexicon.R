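toy_records <- function() {
  tibble::tibble(
    gene_id = c("7", "3", "12"),
    official_symbol = c("CTXN2", "CTXN1", "ALZ1"),
    official_name = c("cortexin-2", "cortexin", "Alzheimer disease"),
    synonyms = list("p40", "p40", character(0)))
}

test_that("variant generation follows the single-dash rule", {
  expect_setequal(generate_variants("cortexin-2"),
                  c("cortexin 2", "cortexin2"))
  expect_equal(generate_variants("tp53"), character(0))
  expect_equal(generate_variants("nf-kappa-b"), character(0))
})

test_that("dictionary construction bans suffixes, merges, and sorts longest-first", {
  dict <- build_dictionary(toy_records())
  # banned suffix removed the Alzheimer name but kept the ALZ1 symbol
  expect_false(any(grepl("disease$", dict$surface, ignore.case = TRUE)))
  expect_true("ALZ1" %in% dict$surface)
  # the shared synonym carries both candidate ids on separate rows
  p40 <- dict[dict$surface == "p40", ]
  expect_setequal(p40$gene_id, c("7", "3"))
  expect_true("p40" %in% ambiguous_surfaces(dict))
  # longest-first, ties lexicographic
  expect_true(all(diff(nchar(dict$surface)) <= 0))
  expect_true(which(dict$surface == "cortexin-2")[1] <
                which(dict$surface == "cortexin")[1])
  # dash variants present, and no variant string contains a dash
  expect_true(all(c("cortexin 2", "cortexin2") %in% dict$surface))
  variants <- setdiff(dict$surface,
                      unlist(c(toy_records()$official_symbol,
                               toy_records()$official_name,
                               toy_records()$synonyms)))
  expect_false(any(grepl("-", variants, fixed = TRUE)))
  # no duplicate (surface, gene_id) pairs
  expect_equal(anyDuplicated(dict[c("surface", "gene_id")]), 0)
  expect_error(build_dictionary(toy_records()[0, ]), "empty")
})

test_that("matching is greedy leftmost-longest at token boundaries", {
  dict <- build_dictionary(toy_records())
  sents <- tibble::tibble(citation_id = "c", position = 1:3,
                          text = c("cortexin 2 binds receptors",
                                   "p40 and CTXN1 interact",
                                   "the subcortexin region"))
  m <- match_mentions(sents, dict, homonyms = character(0), expand = FALSE)
  first <- m[m$position == 1, ]
  expect_equal(first$text, "cortexin 2")
  expect_equal(first$candidate_ids[[1]], "7")
  second <- m[m$position == 2, ]
  expect_equal(second$text, c("p40", "CTXN1"))
  expect_setequal(second$candidate_ids[[1]], c("3", "7"))
  # spans are disjoint
  expect_true(all(second$start[-1] >= second$end[-nrow(second)]))
  # no match inside a longer token ("subcortexin")
  expect_equal(nrow(m[m$position == 3, ]), 0)
})

test_that("homonym surface forms match case-sensitively", {
  records <- tibble::tibble(gene_id = "9", official_symbol = "WAS",
                            official_name = NA_character_,
                            synonyms = list(character(0)))
  dict <- build_dictionary(records)
  sents <- tibble::tibble(citation_id = "c", position = 1:2,
                          text = c("He was tired", "WAS deficiency noted"))
  m <- match_mentions(sents, dict, homonyms = "WAS", expand = FALSE)
  expect_equal(m$position, 2L)
  expect_equal(m$text, "WAS")
  # without the homonym list the lowercase token would match
  m2 <- match_mentions(sents, dict, homonyms = character(0), expand = FALSE)
  expect_equal(m2$position, 1:2)
})

test_that("greedy matching equals the exhaustive leftmost-longest oracle", {
  withr::with_seed(2024, {
    for (i in 1:120) {
      inst <- random_match_instance()
      expect_true(greedy_equals_oracle(inst))
    }
  })
})

test_that("officialness disambiguation prefers symbol over name over synonym", {
  records <- tibble::tibble(
    gene_id = c("5", "2", "8"),
    official_symbol = c("AAA", "BBB", "CCC"),
    official_name = c("alpha factor", "beta factor", "gamma factor"),
    synonyms = list("shared", "shared", character(0)))
  # "shared" is also CCC's official symbol in a second record set
  records2 <- records
  records2$official_symbol[3] <- "shared"
  dict <- build_dictionary(records2)
  sents <- tibble::tibble(citation_id = "c", position = 1L, text = "shared")
  m <- disambiguate_official(
    match_mentions(sents, dict, homonyms = character(0), expand = FALSE),
    dict)
  expect_equal(m$resolved_id, "8")  # official symbol beats synonyms
  # synonym-only tie breaks on the smallest gene id (numeric order)
  dict2 <- build_dictionary(records)
  m2 <- disambiguate_official(
    match_mentions(sents, dict2, homonyms = character(0), expand = FALSE),
    dict2)
  expect_equal(m2$resolved_id, "2")
  # singleton candidate resolves to itself
  sents3 <- tibble::tibble(citation_id = "c", position = 1L, text = "AAA up")
  m3 <- disambiguate_official(
    match_mentions(sents3, dict2, homonyms = character(0), expand = FALSE),
    dict2)
  expect_equal(m3$resolved_id, "5")
})

test_that("profiles are tf-idf over stop-word-filtered tokens", {
  texts <- tibble::tibble(
    gene_id = c("1", "1", "2"),
    text = c("kinase signaling cascade", "kinase activity",
             "ribosome assembly cascade"))
  prof <- build_profiles(texts, stopwords = c("the", "of"))
  p1 <- prof[prof$gene_id == "1", ]
  expect_true(all(c("kinase", "signaling", "activity") %in% p1$term))
  # a term present in every gene's texts has idf log(N/df) = 0
  expect_equal(prof$weight[prof$term == "cascade"], c(0, 0))
  # kinase appears twice for gene 1: tf = 2, idf = log(2)
  expect_equal(prof$weight[prof$gene_id == "1" & prof$term == "kinase"],
               2 * log(2))
  expect_error(build_profiles(tibble::tibble(gene_id = "g", text = "the of"),
                              stopwords = c("the", "of")),
               "stop-word")
})

test_that("context-profile disambiguation picks the closest candidate", {
  profiles <- build_profiles(tibble::tibble(
    gene_id = c("3", "7", "9"),
    text = c("ribosome maturation growth",
             "immunity lymphocyte inhibitor",
             "axon synapse dendrite")))
  dict <- build_dictionary(tibble::tibble(
    gene_id = c("3", "7", "9"), official_symbol = c("G3", "G7", "G9"),
    official_name = NA_character_,
    synonyms = list("p40", "p40", "p40")))
  sents <- tibble::tibble(
    citation_id = "c", position = 1L,
    text = "p40 controls immunity and lymphocyte fate")
  m <- match_mentions(sents, dict, homonyms = character(0), expand = FALSE)
  res <- disambiguate_profile(m, sents, profiles, dict)
  expect_equal(res$resolved_id, "7")
  # disjoint context falls back to officialness (numeric smallest id)
  sents2 <- tibble::tibble(citation_id = "c", position = 1L,
                           text = "p40 measured in plasma")
  m2 <- match_mentions(sents2, dict, homonyms = character(0), expand = FALSE)
  res2 <- disambiguate_profile(m2, sents2, profiles, dict)
  expect_equal(res2$resolved_id, "3")
  # a candidate without a profile falls back too (with a message)
  expect_message(
    res3 <- disambiguate_profile(m, sents, profiles[profiles$gene_id != "7", ],
                                 dict),
    "officialness")
  expect_equal(res3$resolved_id, "3")
})

test_that("profile disambiguation recovers seeded ambiguous mentions", {
  # two genes share a name; contexts are sampled from the true gene's
  # disjoint vocabulary
  vocab_a <- c("ribosome", "maturation", "erbb3", "proliferative", "growth")
  vocab_b <- c("nfkb", "immunity", "lymphocyte", "inhibitor", "antigen")
  profiles <- build_profiles(tibble::tibble(
    gene_id = c("103", "104"),
    text = c(paste(vocab_a, collapse = " "), paste(vocab_b, collapse = " "))))
  dict <- build_dictionary(tibble::tibble(
    gene_id = c("103", "104"), official_symbol = c("GA", "GB"),
    official_name = NA_character_, synonyms = list("p40", "p40")))
  withr::with_seed(31, {
    truth <- sample(c("103", "104"), 200, replace = TRUE)
    sents <- tibble::tibble(
      citation_id = sprintf("m%03d", 1:200), position = 1L,
      text = vapply(truth, function(g) {
        voc <- if (g == "103") vocab_a else vocab_b
        paste("p40 with", paste(sample(voc, 3), collapse = " "))
      }, character(1)))
  })
  m <- match_mentions(sents, dict, homonyms = character(0), expand = FALSE)
  res <- disambiguate_profile(m, sents, profiles, dict)
  acc <- mean(res$resolved_id == truth[match(res$citation_id,
                                             sents$citation_id)])
  expect_gte(acc, 0.95)
})

test_that("gene record and mention files round-trip", {
  f <- tempfile()
  writeLines(c("7\tCTXN2\tcortexin-2\tp40|ctx2",
               "3\tCTXN1\tcortexin\t-"), f)
  recs <- read_gene_records(f)
  expect_equal(recs$gene_id, c("7", "3"))
  expect_equal(recs$synonyms[[1]], c("p40", "ctx2"))
  expect_equal(recs$synonyms[[2]], character(0))
  dict <- build_dictionary(recs)
  fd <- tempfile()
  write_dictionary(dict, fd)
  expect_equal(as.data.frame(readr::read_tsv(fd, col_types = "ccii")),
               as.data.frame(dict))
})
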