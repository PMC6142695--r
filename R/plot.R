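#' Plot an evaluation report
#'
#' Bar chart of precision, recall and F per stratum.
#'
#' @param object A `cid_eval` from [evaluate_relations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cid_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("precision", "recall", "f"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("precision", "recall", "f"),
                        labels = c("P", "R", "F"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL,
                  title = "Entity-level CID evaluation") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Loss per epoch, with the development F-score when available.
#'
#' @param object A `cid_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cid_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot learned attention weights by relation type
#'
#' Box plots of the per-instance attention weights over the four knowledge
#' relation types, split by predicted (or gold) label — the package's view
#' of which knowledge the model found influential.
#'
#' @param predictions Prediction tibble from [predict.cid_model()],
#'   optionally with a `gold` column to facet by.
#' @param by Column to split on (default `"label"`).
#' @return A ggplot object.
#' @export
plot_attention <- function(predictions, by = "label") {
  long <- tidyr::pivot_longer(predictions, dplyr::starts_with("alpha_"),
                              names_to = "relation", values_to = "alpha")
  long$relation <- sub("^alpha_", "", long$relation)
  long <- long[!is.na(long$alpha), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$relation, y = .data$alpha,
                                     fill = .data[[by]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "knowledge relation type", y = "attention weight",
                  fill = by) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
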