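# The saturation engine: every single-nucleotide variant of a CDS, its
# consequence, and its dissimilarity score. One base is mutated at a time
# against the original sequence (no compound variants), giving exactly 3L
# records for an L-nt CDS, ordered by position then alternate base.

#' Consequence class labels
#'
#' The six mutually exclusive consequence classes of a single-nucleotide
#' variant, in display order.
#'
#' @format Character vector of six labels.
#' @export
consequence_classes <- c("synonymous", "same_group_missense",
                         "cross_group_missense", "nonsense",
                         "stop_retained", "stop_loss")

#' Classify the consequence of a substitution
#'
#' Six-way classification of an (original, variant) symbol pair:
#' `synonymous` (same amino acid), `stop_retained` (stop to stop),
#' `nonsense` (amino acid to stop), `stop_loss` (stop to amino acid),
#' `same_group_missense` (different amino acids, one physicochemical group),
#' `cross_group_missense` (otherwise). Vectorised.
#'
#' @param original,variant One-letter symbols or `"*"`.
#' @return Factor with levels [consequence_classes].
#' @examples
#' classify_consequence("C", "*")  # nonsense
#' classify_consequence("M", "I")  # same_group_missense (both hydrophobic)
#' classify_consequence("D", "N")  # cross_group_missense (negative vs polar)
#' @export
classify_consequence <- function(original, variant) {
  og <- residue_group(original)
  vg <- residue_group(variant)
  n <- max(length(original), length(variant))
  original <- rep_len(original, n)
  variant <- rep_len(variant, n)
  og <- rep_len(og, n)
  vg <- rep_len(vg, n)
  out <- dplyr::case_when(
    original == "*" & variant == "*" ~ "stop_retained",
    original == variant ~ "synonymous",
    variant == "*" ~ "nonsense",
    original == "*" ~ "stop_loss",
    og == vg ~ "same_group_missense",
    .default = "cross_group_missense"
  )
  factor(out, levels = consequence_classes)
}

#' Enumerate all single-nucleotide variants of a CDS
#'
#' For each of the L nucleotides, generates the 3 possible substitutions (9
#' per codon), translates the mutated codon against the original frame, and
#' records the consequence and dissimilarity score of each variant. Records
#' are ordered by nucleotide position, then alternate base (A < C < G < T),
#' so output is byte-reproducible.
#'
#' @param cds A CDS (string or [validate_cds()] result).
#' @param matrix Dissimilarity matrix, default the packaged [sneath_matrix()].
#' @param stop_loss_score Score for stop-loss variants (see
#'   [substitution_score()]).
#' @return A tibble of 3L rows with columns `nt_position`, `codon_index`,
#'   `offset_in_codon`, `ref_base`, `alt_base`, `original_codon`,
#'   `variant_codon`, `original_aa`, `variant_aa`, `original_group`,
#'   `variant_group`, `consequence`, `sneath_score`.
#' @examples
#' enumerate_snps("ATGTAA")  # 18 records
#' @export
enumerate_snps <- function(cds, matrix = sneath_matrix(),
                           stop_loss_score = 100L) {
  cds <- validate_cds(cds)
  n <- nchar(cds)
  bases <- strsplit(unclass(cds), "")[[1]]
  codons <- .codons_of(cds)
  nt_position <- rep(seq_len(n), each = 3L)
  ref_base <- bases[nt_position]
  alt_base <- unlist(lapply(bases, function(b) setdiff(c("A", "C", "G", "T"), b)),
                     use.names = FALSE)
  codon_index <- (nt_position - 1L) %/% 3L + 1L
  offset_in_codon <- (nt_position - 1L) %% 3L + 1L
  original_codon <- codons[codon_index]
  variant_codon <- original_codon
  substr(variant_codon, offset_in_codon, offset_in_codon) <- alt_base
  original_aa <- translate_codon(original_codon)
  variant_aa <- translate_codon(variant_codon)
  tibble::tibble(
    nt_position = nt_position,
    codon_index = codon_index,
    offset_in_codon = offset_in_codon,
    ref_base = ref_base,
    alt_base = alt_base,
    original_codon = original_codon,
    variant_codon = variant_codon,
    original_aa = original_aa,
    variant_aa = variant_aa,
    original_group = residue_group(original_aa),
    variant_group = residue_group(variant_aa),
    consequence = classify_consequence(original_aa, variant_aa),
    sneath_score = substitution_score(original_aa, variant_aa, matrix,
                                      stop_loss_score = stop_loss_score)
  )
}

#' Run a full saturation analysis
#'
#' Validates a CDS, enumerates all its single-nucleotide variants, and
#' bundles the per-variant records with the translated protein into a
#' `snp_saturation` object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams enumerate_snps
#' @return An object of class `snp_saturation`: a list with elements `cds`,
#'   `protein`, `records` (the [enumerate_snps()] tibble) and
#'   `stop_loss_score`.
#' @examples
#' sat <- saturate(b2m_cds())
#' sat
#' glance(sat)
#' @export
saturate <- function(cds, matrix = sneath_matrix(), stop_loss_score = 100L) {
  cds <- validate_cds(cds)
  structure(
    list(
      cds = cds,
      protein = translate_cds(cds),
      records = enumerate_snps(cds, matrix, stop_loss_score),
      stop_loss_score = as.integer(stop_loss_score)
    ),
    class = "snp_saturation"
  )
}

#' @export
print.snp_saturation <- function(x, ...) {
  part <- consequence_partition(x$records)
  cat(sprintf("<snp_saturation> %d nt CDS, %d codons, %d variants\n",
              nchar(x$cds), attr(x$cds, "codon_count"), nrow(x$records)))
  cat(paste(sprintf("  %-15s %4d (%.1f%%)", part$bucket, part$n, part$percent),
            collapse = "\n"), "\n")
  invisible(x)
}
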