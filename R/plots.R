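#' Plot an INDEL length spectrum
#'
#' Bar chart of INDEL counts per length bin, CDS versus non-CDS.
#'
#' @param x An `mga_indel_spectrum` from [indel_spectrum()].
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(x) {
  stopifnot(inherits(x, "mga_indel_spectrum"))
  d <- x$spectrum
  lv <- c(as.character(1:50), ">50")
  d$bin <- factor(d$bin, levels = lv[lv %in% d$bin])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$n, fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "INDEL length (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot region alignment metrics
#'
#' Position-match and aligned-base counts per region class.
#'
#' @param metrics Tibble from [region_metrics()].
#' @return A ggplot object.
#' @export
plot_region_metrics <- function(metrics) {
  d <- tidyr::pivot_longer(metrics, c("position_match_bp", "aligned_bp"),
                           names_to = "metric", values_to = "bp")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$bp, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "base pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
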