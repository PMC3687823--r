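# Seeded synthetic corpora with the statistical structure the selection
# method exploits: GeneRIF-positive sentences concentrated at the title and
# the last sentences, a Background -> Objective -> Methods -> Results ->
# Conclusions discourse with section-specific vocabulary, planted gene
# mentions (including ambiguous and dash-containing names), and
# parenthetical abbreviation definitions. Everything is reproducible from
# the seed.

SECTION_VOCAB <- list(
  Background = c("previously", "literature", "reported", "established",
                 "context", "understood", "implicated", "studies"),
  Objective = c("aimed", "sought", "investigate", "hypothesis", "objective",
                "examined", "whether", "determine"),
  Methods = c("assay", "cohort", "measured", "protocol", "samples",
              "immunoblot", "genotyped", "sequencing"),
  Results = c("observed", "increased", "decreased", "significant",
              "correlated", "elevated", "induced", "detected"),
  Conclusions = c("conclude", "suggests", "demonstrates", "supports",
                  "indicates", "therefore", "underscores", "highlights")
)

POSITIVE_VOCAB <- c("novel", "regulates", "modulates", "promotes",
                    "suppresses", "mediates")
NEGATIVE_VOCAB <- c("routine", "baseline", "collected", "enrolled",
                    "recorded", "standard")
SHARED_VOCAB <- c("patients", "tumor", "tissue", "cells", "carcinoma",
                  "clinical", "analysis", "study")

GO_PHRASES <- c("apoptotic process", "signal transduction",
                "regulation of transcription", "kinase activity",
                "cell proliferation", "inflammatory response",
                "dna repair", "cell adhesion")

#' Toy gene inventory used by the synthetic generator
#'
#' Eight synthetic human-style gene records, including a dash-containing
#' official name (variant generation), an ambiguous synonym shared by two
#' genes with disjoint profile vocabularies (disambiguation), a symbol that
#' is also a common English word (homonym case-sensitivity), and a long
#' official name with a parenthetically defined symbol (abbreviation
#' resolution).
#'
#' @return A gene record tibble (see [read_gene_records()]).
#' @export
toy_gene_records <- function() {
  tibble(
    gene_id = c("101", "102", "103", "104", "105", "106", "107", "108"),
    official_symbol = c("CTXN2", "CTXN1", "PA2G4", "NFKBIL1", "VEGFA",
                        "WAS", "TP53", "BRCA1"),
    official_name = c("cortexin-2", "cortexin", "proliferation-associated protein",
                      "NFKB inhibitor like protein", "vascular endothelial growth factor a",
                      "WAS actin nucleation promoting factor",
                      "tumor protein p53", "breast cancer type 1 protein"),
    synonyms = list(character(0), character(0), c("p40", "EBP1"),
                    c("p40", "IKBL"), c("VEGF-A"), c("WASP"),
                    c("p53"), character(0))
  )
}

#' Signal vocabularies of the synthetic generator
#'
#' Every generated sentence carries one signal token. With
#' `vocab_overlap = 0` GeneRIF-positive sentences draw it from the
#' `positive` list and negatives from the `negative` list; as
#' `vocab_overlap` rises toward 1 both classes increasingly draw from the
#' union, erasing the lexical class signal while leaving positional and
#' discourse structure untouched.
#'
#' @return A list with character vectors `positive` and `negative`.
#' @export
generif_signal_vocab <- function() {
  list(positive = POSITIVE_VOCAB, negative = NEGATIVE_VOCAB)
}

#' Per-gene context vocabulary of the toy inventory
#'
#' The word lists the generator samples around each planted gene mention;
#' the ambiguous pair (gene ids 103/104) have disjoint vocabularies so
#' profile disambiguation can recover the truth.
#'
#' @return A named list of character vectors, keyed by gene id.
#' @export
toy_gene_vocab <- function() GENE_VOCAB

# per-gene context vocabulary, disjoint for the ambiguous pair 103/104
GENE_VOCAB <- list(
  "101" = c("cortex", "neuronal", "dendrite"),
  "102" = c("membrane", "synapse", "axon"),
  "103" = c("ribosome", "maturation", "erbb3", "proliferative"),
  "104" = c("nfkb", "inhibitor", "immunity", "lymphocyte"),
  "105" = c("angiogenic", "endothelium", "vascular"),
  "106" = c("actin", "cytoskeleton", "polymerization"),
  "107" = c("checkpoint", "damage", "suppressor"),
  "108" = c("repair", "hereditary", "ovarian")
)

#' Synthetic-corpus configuration
#'
#' Defaults define the study conditions the generator emulates: 400
#' training and 150 testing citations, section lengths giving 6-8
#' sentences per citation, and positive placement odds concentrating
#' GeneRIF sentences at the title and the last two sentences so that about
#' 42% of sentences are positive.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_train,n_test Citations in each split.
#' @param placement_weights Named odds for a sentence being
#'   GeneRIF-positive by position class: `title`, `last_two`, `body`. A
#'   weight `w` gives Bernoulli probability `w / (1 + w)` (19 -> 0.95,
#'   9 -> 0.90, 1/19 -> 0.05).
#' @param section_lengths Named list of `c(min, max)` sentence counts per
#'   canonical section.
#' @param abbrev_prob Probability that a citation introduces its focal gene
#'   with a parenthetical symbol definition and then uses the symbol.
#' @param ambiguous_prob Probability that a citation's focal mention uses
#'   the ambiguous synonym instead of an unambiguous name.
#' @param vocab_overlap In \[0, 1\]: 0 keeps the GeneRIF-positive and
#'   negative signal vocabularies disjoint; 1 makes them identical.
#' @param go_positive_prob,go_negative_prob Probability that a
#'   positive/negative sentence carries a Gene Ontology phrase.
#' @param n_abstracts Structured abstracts for
#'   [generate_structured_abstracts()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_train = 400L, n_test = 150L,
                         placement_weights = c(title = 19, last_two = 9,
                                               body = 1 / 19),
                         section_lengths = list(Background = c(1, 1),
                                                Objective = c(1, 1),
                                                Methods = c(1, 1),
                                                Results = c(1, 2),
                                                Conclusions = c(1, 2)),
                         abbrev_prob = 0.3, ambiguous_prob = 0.25,
                         vocab_overlap = 0, go_positive_prob = 0.5,
                         go_negative_prob = 0.2, n_abstracts = 2000L) {
  stopifnot(all(placement_weights >= 0), any(placement_weights > 0),
            n_train + n_test >= 1,
            vocab_overlap >= 0, vocab_overlap <= 1)
  if (any(vapply(section_lengths, function(r) r[2] < r[1] || r[1] < 0,
                 logical(1)))) {
    abort("synth_config(): invalid section length range")
  }
  if (sum(vapply(section_lengths, function(r) r[2], numeric(1))) < 1) {
    abort("synth_config(): sections allow zero abstract sentences")
  }
  structure(list(seed = as.integer(seed), n_train = n_train, n_test = n_test,
                 placement_weights = placement_weights,
                 section_lengths = section_lengths,
                 abbrev_prob = abbrev_prob, ambiguous_prob = ambiguous_prob,
                 vocab_overlap = vocab_overlap,
                 go_positive_prob = go_positive_prob,
                 go_negative_prob = go_negative_prob,
                 n_abstracts = as.integer(n_abstracts)),
            class = "synth_config")
}

place_prob <- function(w) w / (1 + w)

signal_token <- function(positive, overlap) {
  own <- if (positive) POSITIVE_VOCAB else NEGATIVE_VOCAB
  if (stats::runif(1) < overlap) {
    # overlapping regime draws from the union, erasing the class signal
    sample(c(POSITIVE_VOCAB, NEGATIVE_VOCAB), 1)
  } else {
    sample(own, 1)
  }
}

#' Generate a synthetic GeneRIF corpus
#'
#' Produces citations with full gold annotations: GeneRIF flags placed by
#' the positional odds, 6-way gold discourse labels (the gold vocabulary
#' uses Purpose where predictions use Objective), claim and subcategory
#' labels, planted gene mentions with known true identifiers (ambiguous
#' surface forms are resolvable from the sentence vocabulary), and
#' parenthetical abbreviation definitions. Runs are byte-identical for a
#' given configuration.
#'
#' @param config A [synth_config()].
#' @return A list: `citations` (citation tibble with a `split` column),
#'   `gene_records`, `go_terms`, `gold_mentions` (tibble `citation_id`,
#'   `position`, `surface`, `true_gene_id`), `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  records <- toy_gene_records()
  n <- config$n_train + config$n_test
  with_seed(config$seed, {
    rows <- vector("list", n)
    gold_mentions <- vector("list", n)
    for (i in seq_len(n)) {
      gen <- generate_one_citation(i, config, records)
      rows[[i]] <- gen$citation
      gold_mentions[[i]] <- gen$mentions
    }
    citations <- dplyr::bind_rows(rows)
    citations$split <- rep(c("train", "test"),
                           c(config$n_train, config$n_test))
    list(citations = citations, gene_records = records,
         go_terms = default_go_terms(),
         gold_mentions = dplyr::bind_rows(gold_mentions),
         config = config)
  })
}

generate_one_citation <- function(i, config, records) {
  cid <- sprintf("SYN%04d", i)
  # focal gene; ambiguous citations use the shared synonym "p40"
  ambiguous <- stats::runif(1) < config$ambiguous_prob
  focal <- if (ambiguous) sample(c("103", "104"), 1)
    else sample(setdiff(records$gene_id, c("103", "104")), 1)
  rec <- records[records$gene_id == focal, ]
  surface <- if (ambiguous) "p40" else rec$official_symbol
  use_abbrev <- !ambiguous && stats::runif(1) < config$abbrev_prob &&
    nchar(rec$official_name) > nchar(rec$official_symbol)

  secs <- names(config$section_lengths)
  lens <- vapply(config$section_lengths, function(r) {
    if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
  }, numeric(1))
  section_of <- rep(secs, lens)
  n_abs <- length(section_of)
  n_tot <- n_abs + 1L

  pw <- config$placement_weights
  cls <- c("title", ifelse(seq_len(n_abs) + 1L >= n_tot - 1L,
                           "last_two", "body"))
  p_pos <- place_prob(pw[cls])
  positive <- stats::runif(n_tot) < p_pos

  gvoc <- GENE_VOCAB[[focal]]
  texts <- character(n_tot)
  mention_rows <- list()
  add_mention <- function(pos, surf) {
    mention_rows[[length(mention_rows) + 1]] <<-
      tibble(citation_id = cid, position = pos, surface = surf,
             true_gene_id = focal)
  }
  # title: focal mention + context + signal token
  texts[1] <- paste(surface, "expression", signal_token(positive[1],
                                                        config$vocab_overlap),
                    sample(gvoc, 1), "outcome in",
                    sample(SHARED_VOCAB, 1))
  add_mention(1L, surface)
  for (k in seq_len(n_abs)) {
    pos <- k + 1L
    sec <- section_of[k]
    words <- c(sample(SECTION_VOCAB[[sec]], 3),
               sample(SHARED_VOCAB, 2),
               signal_token(positive[pos], config$vocab_overlap),
               sample(gvoc, 1))
    go_p <- if (positive[pos]) config$go_positive_prob
      else config$go_negative_prob
    if (stats::runif(1) < go_p) {
      words <- append(words, sample(GO_PHRASES, 1),
                      after = sample(length(words), 1))
    }
    mention_here <- sec %in% c("Results", "Conclusions") ||
      stats::runif(1) < 0.3
    if (mention_here) {
      if (use_abbrev && !any(grepl("(", texts, fixed = TRUE))) {
        words <- c(sprintf("%s (%s)", rec$official_name,
                           rec$official_symbol), words)
        add_mention(pos, rec$official_name)
      } else if (use_abbrev && any(grepl("(", texts, fixed = TRUE))) {
        words <- c(words, rec$official_symbol)
        # after expansion the symbol reads as the long form
        add_mention(pos, rec$official_name)
      } else {
        words <- c(words, surface)
        add_mention(pos, surface)
      }
    }
    texts[pos] <- paste0(paste(words, collapse = " "), ".")
  }
  abstract <- paste(texts[-1], collapse = " ")
  gold_discourse_label <- c("Title",
                            ifelse(section_of == "Objective", "Purpose",
                                   section_of))
  claims <- ifelse(positive,
                   sample(c("Established", "Putative"), n_tot,
                          replace = TRUE, prob = c(0.7, 0.3)),
                   "Non-Claim")
  subcat <- ifelse(positive,
                   sample(GOLD_SUBCATEGORY_LEVELS, n_tot, replace = TRUE,
                          prob = c(0.2, 0.4, 0.05, 0.1, 0.05, 0.2)),
                   NA_character_)
  sub_tbl <- tibble(position = which(positive),
                    label = subcat[positive])
  citation <- tibble(
    citation_id = cid,
    journal = "Synthetic Journal of Human Genetics",
    publication_types = list("Journal Article"),
    mesh_headings = list(c("Humans", "Gene Expression")),
    title = texts[1],
    abstract = abstract,
    section_labels = list(NULL),
    gold_generif = list(which(positive)),
    gold_discourse = list(tibble(position = seq_len(n_tot),
                                 label = gold_discourse_label)),
    gold_claim = list(tibble(position = seq_len(n_tot), label = claims)),
    gold_subcategory = list(if (nrow(sub_tbl) > 0) sub_tbl else NULL)
  )
  list(citation = citation, mentions = dplyr::bind_rows(mention_rows))
}

#' Generate labeled structured abstracts for discourse training
#'
#' Abstracts follow the canonical section order with section-specific
#' vocabulary and carry raw headings drawn from common variants (so the
#' heading normalization map is exercised). Output is pre-split 2/3
#' training, 1/3 testing.
#'
#' @param config A [synth_config()]; `n_abstracts` controls the count.
#' @return A list with `citations` (citation tibble with `section_labels`),
#'   `train` and `test` (labeled sentence tibbles: `citation_id`,
#'   `position`, `text`, `label`).
#' @export
generate_structured_abstracts <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  heading_variants <- list(
    Background = c("BACKGROUND", "INTRODUCTION"),
    Objective = c("OBJECTIVE", "AIMS", "PURPOSE"),
    Methods = c("METHODS", "DESIGN"),
    Results = c("RESULTS", "FINDINGS"),
    Conclusions = c("CONCLUSIONS", "CONCLUSION")
  )
  n <- config$n_abstracts
  with_seed(config$seed + 1L, {
    rows <- vector("list", n)
    sent_rows <- vector("list", n)
    for (i in seq_len(n)) {
      cid <- sprintf("SA%05d", i)
      lens <- vapply(config$section_lengths, function(r) {
        if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
      }, numeric(1))
      secs <- names(config$section_lengths)
      section_of <- rep(secs, lens)
      texts <- vapply(section_of, function(sec) {
        paste0(paste(c(sample(SECTION_VOCAB[[sec]], 3),
                       sample(SHARED_VOCAB, 2)), collapse = " "), ".")
      }, character(1))
      ends <- cumsum(lens) + 1L
      starts <- ends - lens + 1L
      keep <- lens > 0
      sections <- tibble(
        heading = vapply(secs[keep], function(s) {
          sample(heading_variants[[s]], 1)
        }, character(1)),
        start = as.integer(starts[keep]), end = as.integer(ends[keep]))
      title <- paste("Structured report on",
                     sample(SHARED_VOCAB, 1), sample(SHARED_VOCAB, 1))
      rows[[i]] <- tibble(
        citation_id = cid, journal = "Synthetic Journal of Human Genetics",
        publication_types = list("Journal Article"),
        mesh_headings = list("Humans"),
        title = title, abstract = paste(texts, collapse = " "),
        section_labels = list(sections),
        gold_generif = list(NULL), gold_discourse = list(NULL),
        gold_claim = list(NULL), gold_subcategory = list(NULL))
      sent_rows[[i]] <- tibble(citation_id = cid,
                               position = seq_along(texts) + 1L,
                               text = unname(texts), label = section_of)
    }
    citations <- dplyr::bind_rows(rows)
    sentences <- dplyr::bind_rows(sent_rows)
    n_train <- floor(2 * n / 3)
    train_ids <- citations$citation_id[seq_len(n_train)]
    list(citations = citations,
         train = sentences %>% filter(.data$citation_id %in% train_ids),
         test = sentences %>% filter(!.data$citation_id %in% train_ids))
  })
}

#' Generate a citation set with planted filter violations
#'
#' Each citation either passes every per-citation filter rule or violates
#' exactly one (and is clean for all rules applied before it), so a filter
#' report can be checked violation-by-violation. The `violation` column
#' records the intended rule (`"none"` for survivors).
#'
#' @param n Number of citations.
#' @param seed Integer seed.
#' @return A citation tibble with an extra `violation` column.
#' @export
generate_filter_testset <- function(n = 200L, seed = 1L) {
  records <- toy_gene_records()
  plain_genes <- c("CTXN2", "VEGFA", "TP53", "BRCA1")
  with_seed(seed, {
    violation <- sample(c("none", "no_abstract", "nonhuman_mesh",
                          "no_gene_mention", "unfocused_review",
                          "publication_type"),
                        n, replace = TRUE,
                        prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    rows <- lapply(seq_len(n), function(i) {
      v <- violation[i]
      genes <- if (v == "unfocused_review") c("CTXN2", "TP53", "BRCA1")
        else sample(plain_genes, 1)
      body <- sprintf("We studied %s in patient samples. Expression of %s was significant.",
                      paste(genes, collapse = " and "), genes[1])
      tibble(
        citation_id = sprintf("FLT%04d", i),
        journal = "Synthetic Journal of Human Genetics",
        publication_types = list(switch(
          v,
          unfocused_review = "Review",
          publication_type = "Letter",
          "Journal Article")),
        mesh_headings = list(if (v == "nonhuman_mesh") c("Mice", "Genes")
                             else c("Humans", "Genes")),
        title = sprintf("Study %d of %s function", i, genes[1]),
        abstract = switch(
          v,
          no_abstract = "",
          no_gene_mention = "We describe a cohort with no molecular profiling. Outcomes were recorded.",
          body),
        section_labels = list(NULL),
        gold_generif = list(NULL), gold_discourse = list(NULL),
        gold_claim = list(NULL), gold_subcategory = list(NULL),
        violation = v)
    })
    out <- dplyr::bind_rows(rows)
    # a no-gene-mention citation must still carry a gene-free title
    out$title[out$violation == "no_gene_mention"] <-
      sprintf("Cohort description %s",
              out$citation_id[out$violation == "no_gene_mention"])
    out
  })
}
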