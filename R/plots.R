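#' Bar chart of the relative variance partition
#'
#' @param object An `esm_vc` fit.
#' @param ... Unused.
#' @return A ggplot: systematic components as percentage shares, in
#'   canonical term order.
#' @exportS3Method ggplot2::autoplot
autoplot.esm_vc <- function(object, ...) {
  shares <- relative_shares(object)
  shares$term <- factor(shares$term, levels = shares$term)
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = .data$term, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of systematic variance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Dot plot of reliabilities by aggregation level
#'
#' @param tab A tibble with columns `level`, `reliability`, optionally
#'   `scale` (as from [reliability_table()] or [plugin_reliabilities()]).
#' @return A ggplot.
#' @export
plot_reliability <- function(tab) {
  tab$level <- factor(tab$level,
                      levels = intersect(c("BC", "BP", "WPD", "WPM"),
                                         unique(tab$level)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$level,
                                         y = .data$reliability))
  if ("scale" %in% names(tab)) {
    p <- p + ggplot2::aes(colour = .data$scale, group = .data$scale) +
      ggplot2::geom_line()
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "aggregation level", y = "reliability") +
    ggplot2::theme_minimal()
}

#' Heatmap of level-specific scale intercorrelations
#'
#' @param object A [correlate_at_levels()] result.
#' @param ... Unused.
#' @return A ggplot, faceted by level.
#' @exportS3Method ggplot2::autoplot
autoplot.esm_level_cors <- function(object, ...) {
  df <- as_tibble(object)
  df$level <- factor(df$level, levels = c("couple", "person", "person_day",
                                          "person_day_moment"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale_a, y = .data$scale_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
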