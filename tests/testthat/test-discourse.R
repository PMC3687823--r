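# small structured-abstract corpus shared by the labeler tests
sa_small <- generate_structured_abstracts(synth_config(seed = 8,
                                                       n_abstracts = 240))

test_that("distilled labels inherit from sections, title is Title", {
  cits <- sa_small$citations[1:20, ]
  sents <- segment_sentences(cits)
  lab <- distill_discourse_labels(cits, sents)
  one <- lab[lab$citation_id == cits$citation_id[1], ]
  expect_equal(one$label[one$position == 1], "Title")
  # every abstract sentence of an accepted citation has a label
  per <- dplyr::count(lab, citation_id)
  n_sent <- dplyr::count(sents, citation_id)
  expect_equal(per$n, n_sent$n[match(per$citation_id, n_sent$citation_id)])
  # heading variants map through the normalization table
  sec <- cits$section_labels[[1]]
  obj_rows <- sec[sec$heading %in% c("OBJECTIVE", "AIMS", "PURPOSE"), ]
  if (nrow(obj_rows) > 0) {
    expect_true(all(lab$label[lab$citation_id == cits$citation_id[1] &
                                lab$position >= obj_rows$start[1] &
                                lab$position <= obj_rows$end[1]] ==
                      "Objective"))
  }
})

test_that("unmapped headings skip the citation; overlaps are an error", {
  cit <- tibble::tibble(
    citation_id = c("D1", "D2"), journal = NA_character_,
    publication_types = list(character(0), character(0)),
    mesh_headings = list(character(0), character(0)),
    title = "T", abstract = "One. Two. Three.",
    section_labels = list(
      tibble::tibble(heading = c("PATIENTS", "RESULTS"),
                     start = c(2L, 3L), end = c(2L, 4L)),
      tibble::tibble(heading = c("BACKGROUND", "RESULTS"),
                     start = c(2L, 3L), end = c(2L, 4L))),
    gold_generif = list(NULL), gold_discourse = list(NULL),
    gold_claim = list(NULL), gold_subcategory = list(NULL))
  sents <- segment_sentences(cit)
  expect_message(lab <- distill_discourse_labels(cit, sents), "skipped")
  expect_equal(attr(lab, "skipped"), "D1")
  expect_setequal(unique(lab$citation_id), "D2")
  expect_equal(lab$label[lab$citation_id == "D2"],
               c("Title", "Background", "Results", "Results"))
  cit$section_labels[[2]]$start[2] <- 2L
  expect_error(distill_discourse_labels(cit[2, ], sents),
               "overlapping")
})

test_that("both labelers recover planted section structure on held-out data", {
  ens <- train_discourse(sa_small$train, "ensemble", seed = 5)
  seqm <- train_discourse(sa_small$train, "sequence", seed = 5)
  for (model in list(ens, seqm)) {
    pred <- predict_discourse(model, sa_small$test)
    ev <- evaluate_discourse(pred, sa_small$test)
    expect_true(all(ev$f_measure >= 0.9),
                info = paste(model$kind, "per-label F:",
                             paste(round(ev$f_measure, 3), collapse = " ")))
  }
})

test_that("training is deterministic given the seed", {
  probe <- sa_small$test[1:40, ]
  e1 <- train_discourse(sa_small$train, "ensemble", seed = 9)
  e2 <- train_discourse(sa_small$train, "ensemble", seed = 9)
  expect_identical(predict_discourse(e1, probe),
                   predict_discourse(e2, probe))
  s1 <- train_discourse(sa_small$train, "sequence", seed = 9)
  s2 <- train_discourse(sa_small$train, "sequence", seed = 9)
  expect_identical(s1$log_transition, s2$log_transition)
  expect_identical(s1$log_emission, s2$log_emission)
})

test_that("degenerate training sets are rejected", {
  only_results <- sa_small$train[sa_small$train$label == "Results", ]
  expect_error(train_discourse(only_results, "ensemble"), "2 distinct")
  few <- sa_small$train[c(which(sa_small$train$label == "Results")[1:20],
                          which(sa_small$train$label == "Methods")[1:3]), ]
  expect_error(train_discourse(few, "ensemble"), "Methods")
  bad <- sa_small$train[1:20, ]
  bad$label[1] <- "Title"
  expect_error(train_discourse(bad, "sequence"), "vocabulary")
})

test_that("position 1 is always (Title, 1.0) and abstention yields Unknown", {
  ens <- train_discourse(sa_small$train, "ensemble", seed = 5)
  sents <- segment_sentences(sa_small$citations[1:5, ])
  pred <- predict_discourse(ens, sents)
  t1 <- pred[pred$position == 1, ]
  expect_true(all(t1$label == "Title"))
  expect_true(all(t1$confidence == 1))
  # no scorer can clear an unreachable threshold: every abstract sentence
  # abstains, titles never do
  strict <- train_discourse(sa_small$train, "ensemble", seed = 5,
                            threshold = 1)
  odd <- tibble::tibble(citation_id = "odd", position = 1:2,
                        text = c("A title", "zzz qqq vvv unrelated jargon"))
  pod <- predict_discourse(strict, odd)
  expect_equal(pod$label, c("Title", "Unknown"))
  # the sequence model never abstains
  seqm <- train_discourse(sa_small$train, "sequence", seed = 5)
  pseq <- predict_discourse(seqm, odd)
  expect_false(any(pseq$label == "Unknown"))
})

test_that("sequence predictions never violate the trained section order", {
  seqm <- train_discourse(sa_small$train, "sequence", seed = 5)
  pred <- predict_discourse(seqm, sa_small$test)
  core <- c("Background", "Objective", "Methods", "Results", "Conclusions")
  order_rank <- setNames(seq_along(core), core)
  violations <- pred %>%
    dplyr::filter(label != "Title") %>%
    dplyr::group_by(citation_id) %>%
    dplyr::summarise(ok = !is.unsorted(order_rank[label]))
  expect_true(all(violations$ok))
  # single-sentence abstracts decode to one label
  single <- tibble::tibble(citation_id = "s", position = 1:2,
                           text = c("T", "previously reported literature."))
  ps <- predict_discourse(seqm, single)
  expect_equal(nrow(ps), 2)
  expect_true(ps$label[2] %in% core)
})

test_that("discourse evaluation computes one-vs-rest P/R/F", {
  gold <- tibble::tibble(citation_id = "c", position = 1:12,
                         label = rep(c("Results", "Methods"), c(6, 6)))
  # 3 true positives and 1 false positive for Results
  pred <- gold
  pred$label <- c(rep("Results", 3), rep("Methods", 3),
                  "Results", rep("Methods", 5))
  ev <- evaluate_discourse(pred, gold, labels = "Results")
  expect_equal(ev$positives, 6)
  expect_equal(ev$tp, 3)
  expect_equal(ev$fp, 1)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$f_measure, 0.6)
  # perfect and all-miss degenerate cases
  evp <- evaluate_discourse(gold, gold, labels = c("Results", "Methods"))
  expect_true(all(evp$precision == 1 & evp$recall == 1 & evp$f_measure == 1))
  unk <- gold
  unk$label <- "Unknown"
  evu <- evaluate_discourse(unk, gold, labels = c("Results", "Methods"))
  expect_true(all(evu$recall == 0))
  expect_error(evaluate_discourse(pred, gold[0, ]), "empty")
})
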