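#' @importFrom ggplot2 ggplot aes geom_col geom_line labs facet_wrap
#'   scale_fill_manual theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a unit-count histogram
#'
#' @param hits Repeat hits.
#' @return A ggplot: repeats per unit count.
#' @export
plot_unit_histogram <- function(hits) {
  h <- unit_histogram(hits)
  ggplot(h, aes(x = factor(.data$n_units), y = .data$n_repeats)) +
    geom_col(fill = "grey30") +
    labs(x = "units per repeat", y = "repeats") +
    theme_minimal()
}

#' Plot composition fractions
#'
#' @param composition Output of [composition_summary()].
#' @return A ggplot faceted by partition.
#' @export
plot_composition <- function(composition) {
  ggplot(composition, aes(x = .data$category, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~partition, scales = "free_x") +
    labs(x = NULL, y = "fraction of repeats") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sequence-logo-style plot of a position frequency matrix
#'
#' Stacked per-position base frequencies scaled by information content
#' (letter-height convention of standard sequence logos).
#'
#' @param object A `g4_pfm` from [build_pfm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g4_pfm <- function(object, ...) {
  d <- tidy(object)
  d$height <- d$frequency * d$info_bits
  ggplot(d, aes(x = factor(.data$position), y = .data$height,
                fill = .data$base)) +
    geom_col(width = 0.8) +
    scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                 G = "#F7B32B", T = "#D62839")) +
    labs(x = "unit position", y = "bits", fill = NULL) +
    theme_minimal()
}
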