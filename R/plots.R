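#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot accuracy by MAF bin for a concordance report
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot: squared dosage correlation per MAF bin.
#' @export
autoplot.concordance_report <- function(object, ...) {
  d <- dplyr::filter(object$by_bin, .data$defined)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$r2, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), show.legend = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "minor allele frequency bin",
                  y = expression(r^2 ~ "(dosage vs validation genotype)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot ROH segments along the chromosome
#'
#' @param object A `roh_segments` tibble.
#' @param ... Unused.
#' @return A ggplot of segment spans per chromosome.
#' @export
autoplot.roh_segments <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(xmin = .data$start / 1e6,
                               xmax = .data$end / 1e6,
                               ymin = as.integer(factor(.data$chrom)) - 0.3,
                               ymax = as.integer(factor(.data$chrom)) + 0.3)) +
    ggplot2::geom_rect(fill = "grey30") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(object$chrom)),
      labels = sort(unique(object$chrom))) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome",
                  title = "Runs of homozygosity") +
    ggplot2::theme_minimal()
}

#' Coverage curves of a pipeline run
#'
#' NRD and pooled accuracy of the target genome across the depth grid.
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$concordance, "depth", "nrd", "r2_pooled"),
    cols = c("nrd", "r2_pooled"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::scale_x_log10(breaks = object$concordance$depth) +
    ggplot2::labs(x = "depth of coverage (x)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the GP-filter trade-off
#'
#' Discordance and heterozygote retention as the GP threshold rises, per
#' depth of coverage.
#' @param result A `pipeline_result`.
#' @return A ggplot.
#' @export
plot_gp_tradeoff <- function(result) {
  d <- tidyr::pivot_longer(result$gp_tradeoff,
                           cols = c("nrd", "het_retention"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value,
                                  colour = factor(.data$depth))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "GP threshold", y = NULL, colour = "depth (x)") +
    ggplot2::theme_minimal()
}
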