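#' Heatmap of family-by-lineage ortholog percentages
#'
#' Tile plot of the [percent_heatmap()] table; darker tiles mean a higher
#' percentage of detected orthologs.
#'
#' @param percent Tibble from [percent_heatmap()].
#' @return A ggplot object.
#' @export
plot_percent_heatmap <- function(percent) {
  ggplot2::ggplot(
    percent,
    ggplot2::aes(x = .data$family, y = .data$lineage, fill = .data$percent)
  ) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#08306b", limits = c(0, 100),
      name = "% orthologs"
    ) +
    ggplot2::labs(x = "channel family", y = "taxonomic lineage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clustergram-style plot of a three-state presence profile
#'
#' Black: one-to-one ortholog present; red: co-ortholog detected; light
#' brown: no orthology detected.
#'
#' @param object An `ic_profile` from [build_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ic_profile <- function(object, ...) {
  states <- factor(object$state, levels = c(0, 1, 2),
                   labels = c("absent", "one-to-one", "co-ortholog"))
  ggplot2::ggplot(
    mutate(tibble::as_tibble(object), state = states),
    ggplot2::aes(x = .data$ic, y = .data$organism, fill = .data$state)
  ) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(
      values = c(absent = "#d8c39b", `one-to-one` = "black",
                 `co-ortholog` = "#b2182b"),
      name = NULL
    ) +
    ggplot2::labs(x = "query channel", y = "organism") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Column-score profile of a pattern scan
#'
#' Stem plot of the per-column contrast score with selected pattern
#' positions highlighted.
#'
#' @param scan A `pattern_scan` from [select_patterns()] or
#'   [family_shared_patterns()].
#' @return A ggplot object.
#' @export
plot_pattern_scores <- function(scan) {
  all_cols <- attr(scan, "all_columns")
  all_cols$selected <- all_cols$column %in% scan$column
  ggplot2::ggplot(
    all_cols,
    ggplot2::aes(x = .data$column, y = .data$score,
                 colour = .data$selected)
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$column, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey65", `TRUE` = "#b2182b"),
      labels = c(`FALSE` = "background", `TRUE` = "selected"),
      name = NULL
    ) +
    ggplot2::labs(x = "alignment column", y = "contrast score") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pattern_scores
#' @param object A `pattern_scan`.
#' @param ... Unused.
#' @export
autoplot.pattern_scan <- function(object, ...) plot_pattern_scores(object)
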