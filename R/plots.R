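# ggplot2 displays of saturation results.

#' Plot the four-way consequence partition
#'
#' Bar chart of the headline partition with percentage labels.
#'
#' @param object A [saturate()] object.
#' @param similarity,stop_fold Passed to [consequence_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(saturate(b2m_cds()))
#' @method autoplot snp_saturation
#' @export
autoplot.snp_saturation <- function(object, similarity = "charged_merged",
                                    stop_fold = "different_group", ...) {
  part <- consequence_partition(object$records, similarity, stop_fold)
  ggplot2::ggplot(part, ggplot2::aes(x = .data$bucket, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$percent)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = NULL, y = "single-nucleotide variants",
                  title = "Consequence partition of the saturation scan") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot original-vs-variant residue frequencies
#'
#' Side-by-side frequencies of each residue in the original protein (per
#' codon, stop included) and in the variant pool (per variant).
#'
#' @param sat A [saturate()] object.
#' @return A ggplot.
#' @export
plot_frequency_shift <- function(sat) {
  frequency_shift(sat$cds, sat$records) |>
    tidyr::pivot_longer(c("pct_original", "pct_variant"),
                        names_to = "source", names_prefix = "pct_",
                        values_to = "percent") |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$aa, -.data$percent),
                                 y = .data$percent, fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue", y = "% of pool", fill = NULL,
                  title = "Residue frequency: original protein vs variant pool") +
    ggplot2::theme_minimal()
}

#' Plot mean dissimilarity per original residue
#'
#' @param sat A [saturate()] object.
#' @return A ggplot.
#' @export
plot_mean_sneath <- function(sat) {
  mean_sneath_by_original(sat$records) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$original_aa, -.data$mean_score),
      y = .data$mean_score, fill = .data$original_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "original residue", y = "mean dissimilarity score",
                  fill = "group",
                  title = "Mean substitution dissimilarity by original residue") +
    ggplot2::theme_minimal()
}
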