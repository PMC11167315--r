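#' Plot a score table
#'
#' Dot-and-line panels of recall, precision and F1 per scoring category,
#' faceted by corpus, coloured by system — the standard at-a-glance view
#' of where each system trades recall against precision. Undefined
#' metrics are simply absent from the panel.
#'
#' @param object A `pii_scores` tibble (the `scores` element of a
#'   [score_manifest()] run), optionally pre-filtered to one tier/policy.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pii_scores
#' @export
autoplot.pii_scores <- function(object,
                                metrics = c("recall", "precision", "f1"),
                                ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$scoring_category,
                               y = .data$value,
                               colour = .data$system_id,
                               group = .data$system_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$metric),
      cols = ggplot2::vars(.data$corpus_id, .data$tier, .data$policy)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "scoring category", y = NULL, colour = "system") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot one corpus evaluation
#'
#' Bars of recall, precision and F1 per scoring category for a single
#' corpus-level evaluation, with the collapsed "ALL" cell alongside.
#'
#' @param object A `pii_corpus_eval` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pii_corpus_eval
#' @export
autoplot.pii_corpus_eval <- function(object, ...) {
  df <- bind_rows(tidy(object), glance(object))
  long <- tidyr::pivot_longer(
    df, cols = c("recall", "precision", "f1"),
    names_to = "metric", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$category, y = .data$value,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "scoring category", y = NULL, fill = NULL,
      title = paste0("Span-level scores (", object$tier, ", ",
                     object$policy, " matching)")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  }
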