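# Discourse labeling of abstract sentences. Labels are distilled from
# structured abstracts (section headings used as distant supervision) and
# two labelers are trained on them: a one-vs-rest boosted-tree ensemble
# (which may abstain) and a linear-chain sequence model (which never does).

#' Distill discourse labels from structured abstracts
#'
#' Every abstract sentence inherits the canonical discourse label of its
#' enclosing section, via a heading normalization map; the title sentence
#' is labeled Title. Citations containing a heading absent from the map are
#' skipped entirely (reported via a message and the `skipped` attribute).
#'
#' @param citations Citation tibble with `section_labels` present.
#' @param sentences Sentence tibble from [segment_sentences()].
#' @param heading_map Named character vector (uppercase heading ->
#'   canonical label); defaults to the packaged map.
#' @return A tibble `citation_id`, `position`, `label` for accepted
#'   citations, with attribute `skipped` (character vector of skipped
#'   citation ids).
#' @export
distill_discourse_labels <- function(citations, sentences,
                                     heading_map = default_heading_map()) {
  skipped <- character(0)
  rows <- purrr::pmap(
    citations[c("citation_id", "section_labels")],
    function(citation_id, section_labels) {
      sec <- section_labels
      if (is.null(sec) || nrow(sec) == 0) {
        skipped <<- c(skipped, citation_id)
        return(NULL)
      }
      ord <- order(sec$start)
      sec <- sec[ord, ]
      if (any(sec$start[-1] <= sec$end[-nrow(sec)])) {
        abort(sprintf("citation %s: overlapping section ranges", citation_id))
      }
      labels <- heading_map[toupper(sec$heading)]
      if (anyNA(labels)) {
        skipped <<- c(skipped, citation_id)
        return(NULL)
      }
      pos <- sentences$position[sentences$citation_id == citation_id]
      covered <- unlist(purrr::map2(sec$start, sec$end, seq))
      lab <- rep(NA_character_, max(pos))
      lab[covered] <- rep(unname(labels), sec$end - sec$start + 1L)
      lab[1] <- "Title"
      keep <- pos[!is.na(lab[pos])]
      tibble(citation_id = citation_id, position = keep,
             label = lab[keep])
    })
  if (length(skipped) > 0) {
    inform(sprintf("distill_discourse_labels(): skipped %d citation(s) with unmapped or missing headings",
                   length(skipped)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

# ---- feature building shared by both labelers ------------------------------

# Bag-of-words + pos + posf design matrix for abstract sentences.
discourse_design <- function(sentences, vocab = NULL,
                             stopwords = default_stopwords()) {
  toks <- tokenize(sentences$text)
  toks <- purrr::map(toks, function(t) t[!t %in% stopwords])
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(toks)))
  }
  idx <- purrr::imap(toks, function(t, i) {
    j <- match(t, vocab)
    j <- j[!is.na(j)]
    if (length(j) == 0) return(NULL)
    cnt <- table(j)
    cbind(i = i, j = as.integer(names(cnt)), x = as.numeric(cnt))
  })
  idx <- do.call(rbind, idx)
  n <- nrow(sentences)
  ntot <- sentences %>%
    group_by(.data$citation_id) %>%
    mutate(nn = max(.data$position)) %>%
    pull(.data$nn)
  bow <- if (is.null(idx)) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, length(vocab)))
  } else {
    Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = idx[, 3],
                         dims = c(n, length(vocab)))
  }
  m <- cbind(Matrix::Matrix(cbind(pos = sentences$position,
                                  posf = ntot - sentences$position),
                            sparse = TRUE), bow)
  colnames(m) <- c("pos", "posf", vocab)
  list(matrix = m, vocab = vocab)
}

#' Train a discourse labeler
#'
#' Two model families are available. `"ensemble"`: one boosted-decision-tree
#' binary scorer per label over bag-of-words + sentence position features
#' (`pos`, `posf`); prediction takes the label with the highest positive
#' posterior and abstains (`Unknown`) when no scorer clears the abstention
#' threshold. `"sequence"`: a linear-chain model over the same per-sentence
#' evidence — Laplace-smoothed multinomial token emissions per label plus
#' maximum-likelihood label-transition weights — decoded per abstract with
#' the Viterbi algorithm, so every sentence receives a label.
#'
#' @param labeled Sentence tibble with a `label` column (join of
#'   [segment_sentences()] and [distill_discourse_labels()]), abstract
#'   sentences only (Title is handled separately at prediction time).
#' @param method `"ensemble"` or `"sequence"`.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param nrounds,max_depth,eta Boosting hyperparameters (ensemble only).
#' @param threshold Ensemble abstention threshold on the posterior.
#' @param min_support Minimum positive sentences per label (ensemble).
#' @param stopwords Stop-word list for the bag-of-words block.
#' @return A `discourse_model` object.
#' @export
train_discourse <- function(labeled, method = c("ensemble", "sequence"),
                            seed = 1L, nrounds = 40, max_depth = 4,
                            eta = 0.3, threshold = 0.5, min_support = 10,
                            stopwords = default_stopwords()) {
  method <- match.arg(method)
  stopifnot(all(c("citation_id", "position", "text", "label")
                %in% names(labeled)))
  bad <- setdiff(unique(labeled$label), discourse_core_levels())
  if (length(bad) > 0) {
    abort(paste0("train_discourse(): labels outside the trainable vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  if (method == "ensemble") {
    train_discourse_ensemble(labeled, seed, nrounds, max_depth, eta,
                             threshold, min_support, stopwords)
  } else {
    train_discourse_sequence(labeled, seed, stopwords)
  }
}

train_discourse_ensemble <- function(labeled, seed, nrounds, max_depth, eta,
                                     threshold, min_support, stopwords) {
  present <- intersect(discourse_core_levels(), unique(labeled$label))
  if (length(present) < 2) {
    abort("train_discourse(): need at least 2 distinct labels")
  }
  support <- table(labeled$label)
  low <- names(support)[support < min_support]
  if (length(low) > 0) {
    abort(sprintf("train_discourse(): label '%s' has %d positive sentences (minimum %d)",
                  low[1], support[low[1]], min_support))
  }
  design <- discourse_design(labeled, stopwords = stopwords)
  scorers <- lapply(present, function(lab) {
    y <- as.numeric(labeled$label == lab)
    with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(design$matrix, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0)
    })
  })
  names(scorers) <- present
  structure(
    list(kind = "ensemble", labels = present, scorers = scorers,
         vocab = design$vocab, threshold = threshold, seed = seed,
         stopwords = stopwords,
         config = list(nrounds = nrounds, max_depth = max_depth, eta = eta)),
    class = "discourse_model")
}

train_discourse_sequence <- function(labeled, seed, stopwords, alpha = 1) {
  labs <- discourse_core_levels()
  labeled <- labeled %>% arrange(.data$citation_id, .data$position)
  if (nrow(labeled) == 0) abort("train_discourse(): empty training set")
  toks <- tokenize(labeled$text)
  toks <- purrr::map(toks, function(t) t[!t %in% stopwords])
  if (any(lengths(split(labeled$position, labeled$citation_id)) == 0)) {
    abort("train_discourse(): empty label sequence")
  }
  vocab <- sort(unique(unlist(toks)))
  # emission counts: label x term
  em <- matrix(0, nrow = length(labs), ncol = length(vocab),
               dimnames = list(labs, vocab))
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (length(t) == 0) next
    cnt <- table(t)
    em[labeled$label[i], names(cnt)] <- em[labeled$label[i], names(cnt)] +
      as.numeric(cnt)
  }
  # position-bucket emissions give the chain the pos/posf evidence
  pb <- matrix(0, nrow = length(labs), ncol = length(position_buckets()),
               dimnames = list(labs, position_buckets()))
  ntot <- labeled %>% group_by(.data$citation_id) %>%
    mutate(nn = dplyr::n()) %>% pull(.data$nn)
  rel <- (labeled %>% group_by(.data$citation_id) %>%
            mutate(r = row_number()) %>% pull(.data$r))
  buck <- position_bucket(rel, ntot)
  for (i in seq_along(buck)) {
    pb[labeled$label[i], buck[i]] <- pb[labeled$label[i], buck[i]] + 1
  }
  # transitions (START/END included), unsmoothed: a transition never seen
  # in training has -Inf weight and is never decoded
  states <- c("__START__", labs, "__END__")
  tr <- matrix(0, nrow = length(states), ncol = length(states),
               dimnames = list(states, states))
  seqs <- split(labeled$label, labeled$citation_id)
  for (s in seqs) {
    path <- c("__START__", s, "__END__")
    for (k in seq_len(length(path) - 1)) {
      tr[path[k], path[k + 1]] <- tr[path[k], path[k + 1]] + 1
    }
  }
  log_em <- log((em + alpha) / rowSums(em + alpha))
  log_pb <- log((pb + alpha) / rowSums(pb + alpha))
  log_tr <- log(tr / pmax(rowSums(tr), 1))
  structure(
    list(kind = "sequence", labels = labs, vocab = vocab,
         log_emission = log_em, log_posbucket = log_pb,
         log_transition = log_tr, seed = seed, stopwords = stopwords,
         config = list(alpha = alpha)),
    class = "discourse_model")
}

position_buckets <- function() c("first", "early", "middle", "late", "last")

position_bucket <- function(rel, ntot) {
  frac <- ifelse(ntot <= 1, 0, (rel - 1) / (ntot - 1))
  out <- rep("middle", length(rel))
  out[frac <= 0.35] <- "early"
  out[frac >= 0.65] <- "late"
  out[rel == 1] <- "first"
  out[rel == ntot] <- "last"
  out
}

#' @export
print.discourse_model <- function(x, ...) {
  cat(sprintf("<discourse_model: %s over %d labels, vocabulary %d terms>\n",
              x$kind, length(x$labels), length(x$vocab)))
  invisible(x)
}

#' Predict discourse labels for segmented citations
#'
#' Position 1 is always `(Title, 1.0)`. For the boosted ensemble, each
#' abstract sentence takes the label of the highest-scoring binary scorer,
#' or `Unknown` when no scorer reaches the abstention threshold; ties break
#' by the fixed label-order priority. The sequence model decodes the whole
#' abstract jointly (Viterbi) and never abstains.
#'
#' @param model A `discourse_model`.
#' @param sentences Sentence tibble from [segment_sentences()].
#' @return A tibble `citation_id`, `position`, `label`, `confidence`.
#' @export
predict_discourse <- function(model, sentences) {
  if (!inherits(model, "discourse_model")) {
    abort("predict_discourse(): model is not a trained discourse_model")
  }
  titles <- sentences %>% filter(.data$position == 1) %>%
    mutate(label = "Title", confidence = 1) %>%
    select("citation_id", "position", "label", "confidence")
  body <- sentences %>% filter(.data$position > 1)
  if (nrow(body) == 0) {
    return(titles %>% arrange(.data$citation_id, .data$position))
  }
  body_pred <- if (model$kind == "ensemble") {
    design <- discourse_design(body, vocab = model$vocab,
                               stopwords = model$stopwords)
    dtest <- xgboost::xgb.DMatrix(design$matrix, nthread = 1)
    scores <- vapply(model$labels, function(lab) {
      predict(model$scorers[[lab]], dtest)
    }, numeric(nrow(body)))
    scores <- matrix(scores, nrow = nrow(body),
                     dimnames = list(NULL, model$labels))
    best <- apply(scores, 1, which.max)   # first max = label-order priority
    conf <- scores[cbind(seq_len(nrow(scores)), best)]
    lab <- model$labels[best]
    lab[conf < model$threshold] <- "Unknown"
    body %>% mutate(label = lab, confidence = conf) %>%
      select("citation_id", "position", "label", "confidence")
  } else {
    decode_sequence(model, body)
  }
  dplyr::bind_rows(titles, body_pred) %>%
    arrange(.data$citation_id, .data$position)
}

decode_sequence <- function(model, body) {
  labs <- model$labels
  out <- body %>% arrange(.data$citation_id, .data$position)
  toks <- tokenize(out$text)
  toks <- purrr::map(toks, function(t) t[t %in% model$vocab &
                                           !t %in% model$stopwords])
  groups <- split(seq_len(nrow(out)), out$citation_id)
  label <- character(nrow(out)); conf <- numeric(nrow(out))
  for (g in groups) {
    n <- length(g)
    ntot <- n
    buck <- position_bucket(seq_len(n), ntot)
    # per-sentence emission scores
    emis <- vapply(seq_len(n), function(k) {
      t <- toks[[g[k]]]
      e <- model$log_posbucket[, buck[k]]
      if (length(t) > 0) {
        cnt <- table(t)
        e <- e + as.numeric(model$log_emission[, names(cnt), drop = FALSE] %*%
                              as.numeric(cnt))
      }
      e
    }, numeric(length(labs)))
    emis <- matrix(emis, nrow = length(labs))
    tr <- model$log_transition
    delta <- matrix(-Inf, nrow = length(labs), ncol = n)
    back <- matrix(0L, nrow = length(labs), ncol = n)
    delta[, 1] <- tr["__START__", labs] + emis[, 1]
    if (n > 1) {
      for (k in 2:n) {
        for (j in seq_along(labs)) {
          sc <- delta[, k - 1] + tr[labs, labs[j]]
          back[j, k] <- which.max(sc)
          delta[j, k] <- sc[back[j, k]] + emis[j, k]
        }
      }
    }
    fin <- delta[, n] + tr[labs, "__END__"]
    if (all(!is.finite(fin))) {
      # no feasible path under the learned transitions: per-sentence argmax
      path <- apply(emis, 2, which.max)
    } else {
      path <- integer(n)
      path[n] <- which.max(fin)
      if (n > 1) for (k in n:2) path[k - 1] <- back[path[k], k]
    }
    label[g] <- labs[path]
    # confidence: softmax margin of the chosen label's emission+transition
    for (k in seq_len(n)) {
      p <- exp(emis[, k] - max(emis[, k]))
      conf[g[k]] <- p[path[k]] / sum(p)
    }
  }
  out %>% mutate(label = label, confidence = conf) %>%
    select("citation_id", "position", "label", "confidence")
}

#' Evaluate discourse predictions per label
#'
#' One-vs-rest counts per canonical label: gold positives, true and false
#' positives, precision, recall, F-measure.
#'
#' @param predictions Tibble from [predict_discourse()] (or any tibble with
#'   `citation_id`, `position`, `label`).
#' @param gold Tibble with `citation_id`, `position`, `label` gold labels.
#' @param labels Labels to report on; defaults to the five trainable ones.
#' @return A tibble with one row per label: `label`, `positives`, `tp`,
#'   `fp`, `precision`, `recall`, `f_measure`.
#' @export
evaluate_discourse <- function(predictions, gold,
                               labels = discourse_core_levels()) {
  if (nrow(gold) == 0) abort("evaluate_discourse(): empty test set")
  joined <- gold %>%
    rename(gold_label = "label") %>%
    left_join(predictions %>% rename(pred_label = "label"),
              by = c("citation_id", "position"))
  purrr::map_dfr(labels, function(lab) {
    positives <- sum(joined$gold_label == lab)
    tp <- sum(joined$gold_label == lab & joined$pred_label == lab,
              na.rm = TRUE)
    fp <- sum(joined$gold_label != lab & joined$pred_label == lab,
              na.rm = TRUE)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (positives > 0) tp / positives else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble(label = lab, positives = positives, tp = tp, fp = fp,
           precision = p, recall = r, f_measure = f)
  })
}
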