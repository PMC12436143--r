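# Aggregations over the per-variant records: the headline four-way partition,
# per-residue substitution tables, frequency shifts between the original
# protein and the variant pool, and mean dissimilarity per original residue.

# round half away from zero, as tables are conventionally printed
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.partition_buckets <- c("no_change", "same_group", "different_group",
                        "stop_gain")

#' Headline four-way consequence partition
#'
#' Collapses the six-way consequence classes into the four headline buckets —
#' no change, substitution within a similar group, substitution across
#' groups, and stop gain — with counts and percentages (one decimal, rounded
#' half-up).
#'
#' Two conventions are configurable. `similarity` controls what "similar
#' group" means for missense variants: `"charged_merged"` (default) treats
#' the positively and negatively charged classes as one charged group, so a
#' charge-to-charge replacement counts as similar; `"strict"` requires the
#' same five-way group. `stop_fold` controls the bucket receiving the
#' terminal stop codon's stop-retained variants. Stop-loss variants always
#' fall in `different_group` (the read-through product has no group to
#' match). The defaults are the unique convention under which the four
#' buckets of the B2M saturation partition its 1080 variants into
#' 239/274/57/510; see the methods vignette.
#'
#' @param records A tibble from [enumerate_snps()] (or [generics::tidy()] of a
#'   [saturate()] object).
#' @param similarity `"charged_merged"` (default) or `"strict"`.
#' @param stop_fold Bucket for stop-retained variants: `"different_group"`
#'   (default), `"no_change"`, or `"stop_gain"`.
#' @return A four-row tibble with `bucket`, `n`, `percent`.
#' @examples
#' b2m_cds() |> enumerate_snps() |> consequence_partition()
#' @export
consequence_partition <- function(records,
                                  similarity = c("charged_merged", "strict"),
                                  stop_fold = c("different_group",
                                                "no_change", "stop_gain")) {
  similarity <- match.arg(similarity)
  stop_fold <- match.arg(stop_fold)
  if (nrow(records) == 0L) {
    stop("no records to partition", call. = FALSE)
  }
  charged <- c("POSITIVE", "NEGATIVE")
  same <- records$consequence == "same_group_missense" |
    (similarity == "charged_merged" &
       records$consequence == "cross_group_missense" &
       records$original_group %in% charged &
       records$variant_group %in% charged)
  bucket <- dplyr::case_when(
    records$consequence == "synonymous" ~ "no_change",
    records$consequence == "nonsense" ~ "stop_gain",
    records$consequence == "stop_retained" ~ stop_fold,
    records$consequence == "stop_loss" ~ "different_group",
    same ~ "same_group",
    .default = "different_group"
  )
  total <- length(bucket)
  tibble::tibble(bucket = factor(bucket, levels = .partition_buckets)) |>
    dplyr::count(.data$bucket, .drop = FALSE) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / total, 1L))
}

#' Variant tally for one original residue
#'
#' Restricted to variants whose original symbol matches, counts how often
#' each variant symbol arises. Totals are 9 times the number of codons of
#' that residue in the CDS.
#'
#' @param records A tibble from [enumerate_snps()].
#' @param symbol One-letter original symbol, or `"*"` for the stop codon.
#' @return A tibble `variant_aa`, `variant_group`, `n` sorted by descending
#'   count (zero rows if the symbol does not occur).
#' @examples
#' b2m_cds() |> enumerate_snps() |> substitution_table("M")
#' @export
substitution_table <- function(records, symbol) {
  stopifnot(length(symbol) == 1L)
  residue_group(symbol)  # validates
  records |>
    dplyr::filter(.data$original_aa == symbol) |>
    dplyr::count(.data$variant_aa, .data$variant_group, sort = TRUE)
}

#' Variant group tally for one original residue
#'
#' As [substitution_table()], aggregated to physicochemical groups.
#'
#' @inheritParams substitution_table
#' @return A tibble `variant_group`, `n`.
#' @examples
#' b2m_cds() |> enumerate_snps() |> group_substitution_table("M")
#' @export
group_substitution_table <- function(records, symbol) {
  substitution_table(records, symbol) |>
    dplyr::count(.data$variant_group, wt = .data$n, sort = TRUE)
}

#' Frequency shift between original protein and variant pool
#'
#' Compares, per symbol, the frequency in the original translation product
#' (counted over all codons including the terminal stop, e.g. 120 for B2M)
#' with the frequency among all variant products (out of 3L variants). Both
#' percentage columns sum to 100.
#'
#' @param cds The CDS the records derive from.
#' @param records The [enumerate_snps()] tibble for that CDS.
#' @return A tibble `aa`, `group`, `n_original`, `pct_original`, `n_variant`,
#'   `pct_variant`, one row per symbol occurring in either column.
#' @export
frequency_shift <- function(cds, records) {
  cds <- validate_cds(cds)
  k <- attr(cds, "codon_count")
  if (nrow(records) != 3L * nchar(cds)) {
    stop("records do not match the CDS: expected ", 3L * nchar(cds),
         " rows, got ", nrow(records), call. = FALSE)
  }
  orig <- residue_composition(translate_cds(cds), include_stop = TRUE) |>
    dplyr::rename(n_original = "n")
  var <- records |>
    dplyr::count(aa = .data$variant_aa, group = .data$variant_group,
                 name = "n_variant")
  dplyr::full_join(orig, var, by = c("aa", "group")) |>
    tidyr::replace_na(list(n_original = 0L, n_variant = 0L)) |>
    dplyr::mutate(
      pct_original = 100 * .data$n_original / k,
      pct_variant = 100 * .data$n_variant / nrow(records),
      .after = "n_original"
    ) |>
    dplyr::relocate("n_variant", .before = "pct_variant") |>
    dplyr::arrange(dplyr::desc(.data$n_original))
}

#' Mean dissimilarity score per original residue
#'
#' Arithmetic mean of the per-variant scores grouped by original symbol; the
#' denominator for each symbol is 9 times its codon count in the CDS.
#' Stop-retained variants contribute 0 (no change) and stop-loss variants the
#' `stop_loss_score` the records were enumerated with.
#'
#' @param records The [enumerate_snps()] tibble.
#' @return A tibble `original_aa`, `original_group`, `n`, `mean_score`,
#'   sorted by descending mean.
#' @examples
#' b2m_cds() |> enumerate_snps() |> mean_sneath_by_original()
#' @export
mean_sneath_by_original <- function(records) {
  if (nrow(records) == 0L) {
    stop("no records", call. = FALSE)
  }
  records |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$sneath_score),
      .by = c("original_aa", "original_group")
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_score))
}
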