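#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_histogram geom_hline
#'   labs theme_minimal autoplot facet_wrap coord_flip
#' @export
ggplot2::autoplot

#' @export
autoplot.khubness_map <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$k)) +
    geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    labs(x = "k (networks per vertex)", y = "vertices",
         title = "Multi-network participation (k-hubness)") +
    theme_minimal()
}

#' @export
autoplot.consensus_map <- function(object, ...) {
  ggplot(object$networks, aes(x = factor(.data$network), y = .data$value)) +
    geom_col(fill = "steelblue") +
    labs(x = "canonical network (17-network partition)",
         y = "consensus correspondence",
         title = "Cross-atlas consensus correspondence") +
    theme_minimal()
}

#' @export
autoplot.scca_model <- function(object, dimension = 1, ...) {
  d <- tidy(object)
  d <- d[d$dimension == dimension & d$weight != 0, ]
  ggplot(d, aes(x = stats::reorder(.data$feature, .data$weight),
                y = .data$weight, fill = .data$side)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~side, scales = "free_y") +
    labs(x = NULL, y = "canonical weight",
         title = sprintf("Sparse CCA dimension %d (r = %.2f)",
                         dimension, object$cors[dimension])) +
    theme_minimal()
}

#' Plot regional test results as a significance bar chart
#'
#' @param stats A tibble from [test_regional_maxT()].
#' @param alpha Significance level for the reference line.
#' @return A ggplot object.
#' @export
plot_regional_stats <- function(stats, alpha = 0.05) {
  ggplot(stats[!is.na(stats$t), ],
         aes(x = stats::reorder(.data$region, .data$t), y = .data$t,
             fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "t statistic",
         title = "Regional deviations (max-T corrected)") +
    theme_minimal()
}

#' Plot a similarity-space embedding of groups relative to a reference
#'
#' @param sim A tibble from [similarity_space()].
#' @return A ggplot object.
#' @export
plot_similarity_space <- function(sim) {
  p <- ggplot(sim, aes(x = .data$r, y = .data$mean_abs_diff)) +
    geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(aes(label = .data$group), vjust = -0.8, size = 3) +
    labs(x = "spatial similarity (Pearson r with reference)",
         y = "magnitude deviation (mean |difference|)") +
    theme_minimal()
  if ("family" %in% names(sim)) p <- p + facet_wrap(~family)
  p
}
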