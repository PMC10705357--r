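# ggplot2 views of the main result types.

#' Bar chart of AS event categories
#'
#' @param as_summary Output of [summarize_as_events()] (non-library form).
#' @return A ggplot object.
#' @export
plot_as_summary <- function(as_summary) {
  as_summary$type <- factor(as_summary$type, levels = as_event_types)
  ggplot2::ggplot(as_summary,
                  ggplot2::aes(x = .data$type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "AS event category", y = "events",
                  title = "Alternative-splicing events by category") +
    ggplot2::theme_minimal()
}

#' Bar chart of locus span length bins
#'
#' @param bins Output of [length_bin_shares()].
#' @return A ggplot object.
#' @export
plot_length_bins <- function(bins) {
  bins$bin <- factor(bins$bin, levels = bins$bin)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$share_pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "locus span", y = "share (%)",
                  title = "Gene-locus length distribution") +
    ggplot2::theme_minimal()
}

#' Histogram of APA sites per gene
#'
#' @param apa_stats Output of [apa_gene_stats()].
#' @return A ggplot object.
#' @export
plot_apa_stats <- function(apa_stats) {
  ggplot2::ggplot(apa_stats, ggplot2::aes(x = .data$n_sites)) +
    ggplot2::geom_bar(fill = "seagreen") +
    ggplot2::labs(x = "poly(A) sites per gene", y = "genes",
                  title = "Alternative polyadenylation per gene") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an isoscope pipeline run
#'
#' @param object An `isoscope_run`.
#' @param ... Unused.
#' @return A ggplot object (AS category bar chart).
#' @exportS3Method ggplot2::autoplot
autoplot.isoscope_run <- function(object, ...) {
  plot_as_summary(object$as_summary)
}
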