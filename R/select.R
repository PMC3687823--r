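# GeneRIF sentence classifiers: Naive Bayes, linear SVM, decision tree,
# and AdaBoost.M1 over tree base learners; top-3 ranking per citation and
# positive-class precision/recall/F evaluation.

SELECTOR_ALGORITHMS <- c("nb", "svm", "tree", "adaboost")

feature_columns <- function(matrix) {
  setdiff(names(matrix), c("citation_id", "position", "gold_generif"))
}

#' Train a GeneRIF sentence selector
#'
#' Fits one of four standard text-categorization learners on a feature
#' matrix from [assemble_features()]: `"nb"` (Gaussian Naive Bayes),
#' `"svm"` (linear-kernel SVM; confidences come from a logistic calibration
#' of the decision margin fitted on training folds), `"tree"` (a CART
#' decision tree, the classic C4.5-style single-tree baseline), or
#' `"adaboost"` (AdaBoost.M1 with tree base learners). Zero-variance
#' feature columns are dropped at fit time and recorded on the model.
#'
#' @param matrix Feature tibble with a logical `gold_generif` label column;
#'   both classes must be present.
#' @param algorithm One of `"nb"`, `"svm"`, `"tree"`, `"adaboost"`.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param rounds AdaBoost rounds (default 10).
#' @param tree_control `rpart.control` for tree-based learners; default
#'   leaves depth unrestricted for boosting.
#' @return A `selector_model` object.
#' @export
train_selector <- function(matrix, algorithm = c("nb", "svm", "tree",
                                                 "adaboost"),
                           seed = 1L, rounds = 10, tree_control = NULL) {
  algorithm <- match.arg(algorithm)
  if (!"gold_generif" %in% names(matrix) ||
      anyNA(matrix$gold_generif)) {
    abort("train_selector(): matrix needs a complete gold_generif label column")
  }
  y <- factor(ifelse(matrix$gold_generif, "pos", "neg"),
              levels = c("neg", "pos"))
  if (dplyr::n_distinct(y) < 2) {
    abort("train_selector(): both classes must be present in the labels")
  }
  cols <- feature_columns(matrix)
  x <- as.data.frame(matrix[cols])
  keep <- vapply(x, function(col) stats::var(col) > 0, logical(1))
  if (!any(keep)) abort("train_selector(): all feature columns are constant")
  x <- x[keep]
  fit <- with_seed(seed, switch(
    algorithm,
    nb = e1071::naiveBayes(x, y),
    svm = e1071::svm(x, y, kernel = "linear", probability = TRUE,
                     scale = TRUE),
    tree = rpart::rpart(
      y ~ ., data = cbind(x, y = y), method = "class",
      control = tree_control %||% rpart::rpart.control(xval = 0)),
    adaboost = fit_adaboost(x, y, rounds = rounds,
                            control = tree_control %||%
                              rpart::rpart.control(maxdepth = 30, cp = 0,
                                                   minsplit = 5, xval = 0))
  ))
  structure(list(algorithm = algorithm, fit = fit, features = names(x),
                 all_features = cols, seed = seed, rounds = rounds),
            class = "selector_model")
}

# Classic AdaBoost.M1 loop with rpart stumps/trees as the base learner.
fit_adaboost <- function(x, y, rounds, control) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  data <- cbind(x, y = y)
  for (t in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = data, weights = w, method = "class",
                        control = control)
    pred <- predict(fit, x, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    learners[[length(learners) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(learners) == 0) {
    # degenerate: single unweighted tree
    learners <- list(rpart::rpart(y ~ ., data = data, method = "class",
                                  control = control))
    alphas <- 1
  }
  list(learners = learners, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  votes <- vapply(seq_along(fit$learners), function(t) {
    as.numeric(predict(fit$learners[[t]], x, type = "class") == "pos")
  }, numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}

#' @export
print.selector_model <- function(x, ...) {
  cat(sprintf("<selector_model: %s over %d features (seed %d)>\n",
              x$algorithm, length(x$features), x$seed))
  invisible(x)
}

#' Predict GeneRIF sentences
#'
#' @param object A `selector_model`.
#' @param matrix Feature tibble whose columns match the model's feature
#'   configuration (an error names any missing columns).
#' @param ... Unused.
#' @return A tibble `citation_id`, `position`, `generif` (logical),
#'   `confidence` (positive-class score in \[0, 1\]).
#' @export
predict.selector_model <- function(object, matrix, ...) {
  # deserialized fits need the fitting package's S3 methods registered
  requireNamespace(switch(object$algorithm, nb = "e1071", svm = "e1071",
                          "rpart"), quietly = TRUE)
  missing <- setdiff(object$all_features, names(matrix))
  if (length(missing) > 0) {
    abort(paste0("predict(): matrix is missing feature column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(matrix[object$features])
  conf <- switch(
    object$algorithm,
    nb = predict(object$fit, x, type = "raw")[, "pos"],
    svm = {
      p <- predict(object$fit, x, probability = TRUE)
      attr(p, "probabilities")[, "pos"]
    },
    tree = predict(object$fit, x, type = "prob")[, "pos"],
    adaboost = predict_adaboost(object$fit, x)
  )
  conf <- pmin(pmax(as.numeric(conf), 0), 1)
  tibble(citation_id = matrix$citation_id, position = matrix$position,
         generif = conf >= 0.5, confidence = conf)
}

#' Rank the top GeneRIF candidate sentences per citation
#'
#' Curators are shown the top three candidate sentences by classifier
#' confidence; ties break toward the earlier sentence.
#'
#' @param model A `selector_model`.
#' @param matrix Feature tibble covering the citations to rank.
#' @param k Number of sentences per citation (default 3).
#' @return A tibble `citation_id`, `position`, `confidence`, at most `k`
#'   rows per citation, confidence descending.
#' @export
rank_top3 <- function(model, matrix, k = 3) {
  predict(model, matrix) %>%
    group_by(.data$citation_id) %>%
    arrange(dplyr::desc(.data$confidence), .data$position,
            .by_group = TRUE) %>%
    slice_head(n = k) %>%
    ungroup() %>%
    select("citation_id", "position", "confidence")
}

#' Precision/recall/F from confusion counts
#'
#' Positive-class measures with the degenerate conventions: precision is 0
#' when nothing is predicted positive, recall is 0 when there are no gold
#' positives, and F is 0 whenever P + R = 0.
#'
#' @param tp,fp,fn Non-negative confusion counts.
#' @return A one-row `rif_eval` tibble: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_measure`.
#' @export
prf_from_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  out <- tibble(tp = tp, fp = fp, fn = fn,
                precision = p, recall = r, f_measure = f)
  class(out) <- c("rif_eval", class(out))
  out
}

#' Evaluate a selector on a labeled feature matrix
#'
#' Precision, recall and F-measure on the GeneRIF-positive class.
#'
#' @param model A `selector_model`.
#' @param matrix Feature tibble with a `gold_generif` label column.
#' @return A one-row `rif_eval` tibble (see [prf_from_counts()]).
#' @export
evaluate_selector <- function(model, matrix) {
  if (nrow(matrix) == 0) abort("evaluate_selector(): empty test set")
  if (!"gold_generif" %in% names(matrix) || anyNA(matrix$gold_generif)) {
    abort("evaluate_selector(): matrix needs a complete gold_generif column")
  }
  pred <- predict(model, matrix)
  gold <- matrix$gold_generif
  tp <- sum(pred$generif & gold)
  fp <- sum(pred$generif & !gold)
  fn <- sum(!pred$generif & gold)
  if (tp + fp == 0) {
    inform("evaluate_selector(): no positive predictions; precision defined as 0")
  }
  prf_from_counts(tp, fp, fn)
}

#' GeneRIF class balance of a label set
#'
#' @param x A logical vector of GeneRIF flags, or a data frame with a
#'   `gold_generif` column.
#' @return A one-row tibble: `total`, `positives`, `negatives`,
#'   `pct_positive`, `pct_negative` (percentages rounded to 2 decimals).
#' @export
#' @examples
#' class_balance(rep(c(TRUE, FALSE), c(829, 1158)))
class_balance <- function(x) {
  if (is.data.frame(x)) x <- x$gold_generif
  stopifnot(is.logical(x), length(x) > 0)
  x <- x[!is.na(x)]
  total <- length(x)
  pos <- sum(x)
  tibble(total = total, positives = pos, negatives = total - pos,
         pct_positive = round(100 * pos / total, 2),
         pct_negative = round(100 * (total - pos) / total, 2))
}
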