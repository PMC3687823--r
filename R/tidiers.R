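# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# result types.

#' Tidy a selector model
#'
#' For Naive Bayes, per-feature class-conditional means and standard
#' deviations; for the tree, the variable importances; for AdaBoost, the
#' per-round weights; for the SVM, the (scaled-space) primal coefficients.
#'
#' @param x A `selector_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy selector_model
#' @export
tidy.selector_model <- function(x, ...) {
  switch(
    x$algorithm,
    nb = purrr::imap_dfr(x$fit$tables, function(tab, feat) {
      tibble(term = feat, class = rownames(tab),
             mean = tab[, 1], sd = tab[, 2])
    }),
    tree = {
      imp <- x$fit$variable.importance
      if (is.null(imp)) return(tibble(term = character(),
                                      importance = numeric()))
      tibble(term = names(imp), importance = unname(imp))
    },
    adaboost = tibble(round = seq_along(x$fit$alphas),
                      alpha = x$fit$alphas),
    svm = {
      w <- crossprod(x$fit$coefs, x$fit$SV)
      tibble(term = colnames(w), weight = as.numeric(w))
    }
  )
}

#' @rdname tidy.selector_model
#' @method glance selector_model
#' @export
glance.selector_model <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_features = length(x$features),
         seed = x$seed)
}

#' Tidy a discourse model
#'
#' For the sequence model, the label-transition weights in long form; for
#' the ensemble, per-label scorer summaries.
#'
#' @param x A `discourse_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy discourse_model
#' @export
tidy.discourse_model <- function(x, ...) {
  if (x$kind == "sequence") {
    tr <- x$log_transition
    as_tibble(as.data.frame.table(tr, responseName = "log_weight")) %>%
      rename(from = "Var1", to = "Var2") %>%
      mutate(from = as.character(.data$from), to = as.character(.data$to))
  } else {
    tibble(label = x$labels, n_trees = x$config$nrounds)
  }
}

#' @rdname tidy.discourse_model
#' @method glance discourse_model
#' @export
glance.discourse_model <- function(x, ...) {
  tibble(kind = x$kind, n_labels = length(x$labels),
         vocabulary = length(x$vocab), seed = x$seed)
}

#' Tidy a filter report
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return A tibble of per-rule removal counts, with input and survivor
#'   rows included.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(rule = "input", removed = NA_integer_, remaining = x$input),
    x$rules %>% mutate(remaining = x$input - cumsum(.data$removed))
  )
}

#' @rdname tidy.filter_report
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble(input = x$input, removed = sum(x$rules$removed),
         survivors = nrow(x$survivors))
}

#' Plot positive-class evaluation measures
#'
#' @param object A `rif_eval` one-row tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rif_eval
#' @export
autoplot.rif_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("precision", "recall", "f_measure")],
    dplyr::everything(), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "GeneRIF-positive class performance") +
    ggplot2::theme_minimal()
}

#' Plot the GeneRIF frequency by sentence position
#'
#' The characteristic shape of the task: GeneRIF-positive sentences
#' concentrate at the title (position 1) and the final sentences.
#'
#' @param sentences Sentence tibble with `gold_generif`.
#' @return A ggplot of positive counts per sentence position.
#' @export
plot_position_distribution <- function(sentences) {
  counts <- sentences %>%
    filter(!is.na(.data$gold_generif)) %>%
    group_by(.data$position) %>%
    summarise(generifs = sum(.data$gold_generif), .groups = "drop")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$position,
                                       y = .data$generifs)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "sentence position (1 = title)",
                  y = "GeneRIF sentences") +
    ggplot2::theme_minimal()
}

#' Plot per-label discourse evaluation
#'
#' @param object A tibble from [evaluate_discourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot_discourse_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("label", "precision", "recall", "f_measure")],
    -"label", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
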