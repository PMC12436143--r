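# Sequence input, tabular output, packaged fixtures, and the seeded random
# CDS generator used by the property tests.

#' Read a nucleotide sequence from file or literal
#'
#' Accepts a single-record FASTA file, a plain-text sequence file (line
#' breaks and whitespace ignored), or a literal sequence string via `text`.
#' Exactly one of `path`/`text` must be supplied. Multi-record FASTA is an
#' error: the engine analyses one CDS per run.
#'
#' @param path Path to a FASTA or plain-text sequence file.
#' @param text Literal sequence string.
#' @return The raw sequence as a single uppercase-insensitive string (not yet
#'   validated; pass to [validate_cds()]).
#' @export
read_sequence <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text)) {
    stop("supply exactly one of `path` or `text`", call. = FALSE)
  }
  if (!is.null(text)) {
    return(gsub("[[:space:]]", "", text))
  }
  if (!file.exists(path)) {
    stop("cannot read sequence file: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, ">")) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L) {
      stop("expected a single-record FASTA, found ", length(set), " records",
           call. = FALSE)
    }
    message("read FASTA record: ", names(set)[1L])
    return(as.character(set[[1L]]))
  }
  gsub("[[:space:]]", "", paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Packaged B2M fixtures
#'
#' The mature beta-2-microglobulin coding sequence (360 nt, ATG through TAA;
#' RefSeq NM_004048.4 CDS) and its 119-residue protein, the worked example of
#' the package.
#'
#' @return A single sequence string.
#' @examples
#' nchar(b2m_cds())      # 360
#' nchar(b2m_protein())  # 119
#' @export
b2m_cds <- function() {
  path <- system.file("extdata", "b2m_cds.fasta", package = "snpsat",
                      mustWork = TRUE)
  as.character(Biostrings::readDNAStringSet(path)[[1L]])
}

#' @rdname b2m_cds
#' @export
b2m_protein <- function() {
  path <- system.file("extdata", "b2m_protein.fasta", package = "snpsat",
                      mustWork = TRUE)
  as.character(Biostrings::readAAStringSet(path)[[1L]])
}

#' Generate a random valid CDS
#'
#' Draws a CDS of `n_codons` codons: ATG start, a uniformly chosen stop
#' codon at the end, and internal codons drawn uniformly from the 60 sense
#' codons other than ATG's competitors — i.e. any of the 61 sense codons —
#' so no internal stop can arise by construction (no rejection sampling).
#' Deterministic for a fixed seed.
#'
#' @param n_codons Total codon count including start and stop; at least 2.
#' @param seed Integer seed.
#' @return A validated [validate_cds()] object.
#' @examples
#' generate_random_cds(5, seed = 1)
#' @export
generate_random_cds <- function(n_codons, seed) {
  if (n_codons < 2L) {
    stop("a CDS needs at least 2 codons (start + stop)", call. = FALSE)
  }
  code <- genetic_code()
  sense <- code$codon[code$aa != "*"]
  stops <- code$codon[code$aa == "*"]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  internal <- if (n_codons > 2L) sample(sense, n_codons - 2L, replace = TRUE) else character()
  validate_cds(paste(c("ATG", internal, sample(stops, 1L)), collapse = ""))
}

#' Write / read a per-variant table
#'
#' Writes the [enumerate_snps()] tibble as TSV (default) or CSV with the
#' fixed column order, and reads it back with the same types, so a round
#' trip reproduces every field.
#'
#' @param records The records tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `write_snp_table()` returns `path` invisibly; `read_snp_table()`
#'   the records tibble.
#' @export
write_snp_table <- function(records, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  out <- dplyr::mutate(records, consequence = as.character(.data$consequence))
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  spec <- readr::cols(
    nt_position = "i", codon_index = "i", offset_in_codon = "i",
    ref_base = "c", alt_base = "c", original_codon = "c", variant_codon = "c",
    original_aa = "c", variant_aa = "c", original_group = "c",
    variant_group = "c", consequence = "c", sneath_score = "i"
  )
  tab <- if (format == "tsv") {
    readr::read_tsv(path, col_types = spec, progress = FALSE)
  } else {
    readr::read_csv(path, col_types = spec, progress = FALSE)
  }
  dplyr::mutate(tab, consequence = factor(.data$consequence,
                                          levels = consequence_classes))
}

#' Run the full pipeline and write outputs
#'
#' Validates the input, enumerates variants, and writes the per-variant
#' table plus summary tables (partition, variant counts, mean score per
#' original residue) to `out_dir`. Thin wrapper used by the command-line
#' script.
#'
#' @param path,text Input sequence (exactly one; see [read_sequence()]).
#' @param matrix_path Optional dissimilarity-matrix file overriding the
#'   packaged one.
#' @param out_dir Output directory, created if needed.
#' @param format `"tsv"` or `"csv"`.
#' @param similarity,stop_fold Partition conventions, see
#'   [consequence_partition()].
#' @param stop_loss_score See [substitution_score()].
#' @return The [saturate()] object, invisibly.
#' @export
run_saturation <- function(path = NULL, text = NULL, matrix_path = NULL,
                           out_dir = ".", format = c("tsv", "csv"),
                           similarity = "charged_merged",
                           stop_fold = "different_group",
                           stop_loss_score = 100L) {
  format <- match.arg(format)
  matrix <- if (is.null(matrix_path)) sneath_matrix() else read_sneath_matrix(matrix_path)
  sat <- saturate(read_sequence(path, text), matrix, stop_loss_score)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- paste0(".", format)
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  write_snp_table(sat$records, file.path(out_dir, paste0("snp_records", ext)),
                  format)
  writer(consequence_partition(sat$records, similarity, stop_fold),
         file.path(out_dir, paste0("partition", ext)), progress = FALSE)
  writer(frequency_shift(sat$cds, sat$records),
         file.path(out_dir, paste0("frequency_shift", ext)), progress = FALSE)
  writer(mean_sneath_by_original(sat$records),
         file.path(out_dir, paste0("mean_sneath", ext)), progress = FALSE)
  message(sprintf("CDS: %d nt, %d codons; %d variants written to %s",
                  nchar(sat$cds), attr(sat$cds, "codon_count"),
                  nrow(sat$records), out_dir))
  invisible(sat)
}
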