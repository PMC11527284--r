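# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_col facet_wrap labs
#'   scale_y_continuous position_dodge coord_flip geom_line geom_point
NULL

#' Plot a stress profile
#'
#' Grouped bars of the five stress-feature probabilities per mixed-label
#' category.
#'
#' @param object A `"stress_profile"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$feature, y = .data$probability,
                     fill = .data$feature)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~category) +
    labs(x = NULL, y = "feature probability",
         title = "Stress-feature distribution by category")
}

#' Plot top feature words
#'
#' @param object A `"stress_features"` object.
#' @param top_n Words per feature (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_features <- function(object, top_n = 10, ...) {
  tw <- feature_top_words(object, top_n)
  tw$token <- stats::reorder(paste(tw$feature, tw$token, sep = "\r"),
                             tw$probability)
  ggplot(tw, aes(x = .data$token, y = .data$probability)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~feature, scales = "free_y") +
    ggplot2::scale_x_discrete(labels = function(x) sub("^.*\r", "", x)) +
    labs(x = NULL, y = "word probability",
         title = "High-probability words per stress feature")
}

#' Plot entity-level evaluation metrics
#'
#' @param object A `"ner_eval"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ner_eval <- function(object, ...) {
  m <- tidyr::pivot_longer(object$metrics,
                           c("precision", "recall", "f1"),
                           names_to = "metric", values_to = "value")
  ggplot(m, aes(x = .data$entity_type, y = .data$value,
                fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = "Entity-level evaluation")
}

#' Plot the topic-count selection curve
#'
#' Mean held-out perplexity per candidate K with a point at the selection.
#'
#' @param selection The list returned by [select_topic_count()].
#' @return A ggplot object.
#' @export
plot_topic_selection <- function(selection) {
  tab <- selection$table
  ggplot(tab, aes(x = .data$K, y = .data$mean_perplexity)) +
    geom_line() +
    geom_point() +
    geom_point(data = tab[tab$K == selection$K, , drop = FALSE],
               colour = "red", size = 3) +
    labs(x = "number of topics K", y = "held-out perplexity",
         title = "Topic-count selection")
}
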