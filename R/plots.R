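# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_col
#'   geom_histogram facet_wrap labs theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `hkera_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hkera_roc <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `hkera_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot of test metrics by fold.
#' @export
autoplot.hkera_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report,
                              cols = -"fold",
                              names_to = c("set", "metric"),
                              names_sep = "_",
                              values_to = "percent")
  ggplot(long, aes(x = factor(.data$fold), y = .data$percent, fill = .data$set)) +
    geom_col(position = "dodge") +
    facet_wrap(~metric) +
    labs(x = "fold", y = "percent", fill = NULL) +
    theme_minimal()
}

#' Distribution of classifier scores by gene class
#'
#' @param scores Score tibble from [score_genes()].
#' @param truth Tibble `gene_id`, `class` (e.g. synthetic truth).
#' @param bins Histogram bins (default 40).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores, truth, bins = 40) {
  df <- left_join(scores, truth, by = "gene_id")
  ggplot(df, aes(x = .data$score, fill = .data$class)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.55) +
    labs(x = "classifier score", y = "genes", fill = NULL) +
    theme_minimal()
}

#' Mean tensor components by gene class
#'
#' Bar chart of the 16 mean attribute values per class, the per-class
#' contrast that makes the classifier work.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param truth Tibble `gene_id`, `class`.
#' @return A ggplot.
#' @export
plot_components <- function(features, truth) {
  df <- left_join(features, truth, by = "gene_id") |>
    tidyr::pivot_longer(cols = dplyr::any_of(component_names()),
                        names_to = "component", values_to = "value") |>
    group_by(.data$class, .data$component) |>
    summarise(mean_value = mean(.data$value), .groups = "drop") |>
    mutate(component = factor(.data$component, levels = component_names()))
  ggplot(df, aes(x = .data$component, y = .data$mean_value, fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "mean signed component", fill = NULL) +
    theme_minimal()
}
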