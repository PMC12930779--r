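#' Plot a recall-at-effort curve
#'
#' @param x A `recall_curve` tibble from [recall_curve()].
#' @param ... Unused.
#' @return A ggplot object: recall against fraction of the ranked list
#'   screened, with the diagonal (random screening) for reference.
#' @method autoplot recall_curve
#' @export
autoplot.recall_curve <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$effort, y = .data$recall)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Fraction of ranked list screened",
                  y = "Recall of eligible records") +
    ggplot2::theme_minimal()
}

#' @export
plot.recall_curve <- function(x, ...) print(autoplot.recall_curve(x, ...))

#' Rank distributions of eligible vs ineligible records
#'
#' Boxplots of ranking position by gold label with an inverted y axis, so
#' more relevant (lower-ranked) records sit higher — the usual way screening
#' prioritisation quality is eyeballed.
#'
#' @param ranking A `ranking` tibble.
#' @param labels Gold labels (tibble with `record_id`, `gold_label` or named
#'   vector).
#' @return A ggplot object.
#' @export
plot_rank_distribution <- function(ranking, labels) {
  eligible <- join_labels(ranking, labels)
  df <- tibble::tibble(
    rank = ranking$rank,
    gold_label = ifelse(eligible, "eligible", "ineligible")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gold_label, y = .data$rank)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Term-score rank (lower = more relevant)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
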