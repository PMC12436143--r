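# broom-style methods for snp_saturation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a saturation result
#'
#' `tidy()` returns the per-variant records, one row per single-nucleotide
#' variant; `glance()` a one-row summary with sequence sizes, the four-way
#' partition (default conventions), and the overall mean score.
#'
#' @param x A [saturate()] object.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' sat <- saturate("ATGTGCTAA")
#' tidy(sat)
#' glance(sat)
#' @method tidy snp_saturation
#' @export
tidy.snp_saturation <- function(x, ...) {
  x$records
}

#' @rdname tidy.snp_saturation
#' @method glance snp_saturation
#' @export
glance.snp_saturation <- function(x, ...) {
  part <- consequence_partition(x$records)
  wide <- stats::setNames(as.list(part$n), paste0("n_", part$bucket))
  tibble::tibble(
    n_nt = nchar(x$cds),
    n_codons = attr(x$cds, "codon_count"),
    n_residues = nchar(x$protein),
    n_snps = nrow(x$records),
    !!!wide,
    mean_sneath = mean(x$records$sneath_score)
  )
}
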