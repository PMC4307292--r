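#' Plot a block segmentation
#'
#' Draws the blocks along the locus axis as rectangles filled by their
#' diversity, with gaps (loci outside any block) left blank.
#'
#' @param object a `hap_segmentation`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hap_segmentation <- function(object, ...) {
  df <- as_tibble(unclass_seg(object))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = 0, ymax = 1,
                                    fill = .data$delta),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_gradient(name = expression(delta),
                                 low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "SNP locus",
                  y = NULL,
                  title = sprintf("%d haplotype blocks (D = %s, W = %d)",
                                  nrow(df), format(attr(object, "D")),
                                  attr(object, "W"))) +
    ggplot2::theme_minimal()
}

#' Plot block and tagSNP coverage efficiency
#'
#' Line plots of the [coverage_tables()] summary: blocks needed and
#' tagSNPs needed per 10% increment of the covered region, and the number
#' of covered SNPs per tagSNP.
#'
#' @param seg a `hap_segmentation` with tagSNP columns.
#' @return a ggplot object (facetted).
#' @export
plot_coverage <- function(seg) {
  cov <- coverage_tables(seg)
  long <- tidyr::pivot_longer(
    cov[, c("coverage_pct", "pct_blocks", "pct_tags", "snps_per_tag")],
    cols = -"coverage_pct", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$coverage_pct,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = "% of covered region", y = NULL) +
    ggplot2::theme_minimal()
}
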