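# Coding-sequence validation and translation. A CDS runs from the ATG start
# codon through the terminal stop codon, in frame, with no internal stop.

#' Validate a coding sequence
#'
#' Normalises (whitespace stripped, case folded, U read as T) and validates a
#' nucleotide string as a complete CDS: alphabet A/C/G/T, length divisible by
#' 3, first codon ATG, last codon a stop, no internal stop. Each violation is
#' a distinct, position-reporting error.
#'
#' @param raw A nucleotide string (may contain whitespace/newlines).
#' @return The normalised sequence as a length-1 character with class
#'   `"cds"` and attribute `codon_count`.
#' @examples
#' validate_cds("ATG TGC taa")
#' cds <- validate_cds(b2m_cds())
#' attr(cds, "codon_count")  # 120
#' @export
validate_cds <- function(raw) {
  if (inherits(raw, "cds")) {
    return(raw)
  }
  if (!is.character(raw) || length(raw) != 1L) {
    stop("expected a single nucleotide string", call. = FALSE)
  }
  seq <- gsub("[[:space:]]", "", raw)
  seq <- .normalize_bases(seq, what = "CDS")
  n <- nchar(seq)
  if (n == 0L) {
    stop("empty sequence", call. = FALSE)
  }
  if (n %% 3L != 0L) {
    stop(sprintf("CDS length %d is not divisible by 3", n), call. = FALSE)
  }
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1L] != "ATG") {
    stop(sprintf("CDS must start with ATG; found %s at codon 1", codons[1L]),
         call. = FALSE)
  }
  aa <- translate_codon(codons)
  k <- length(codons)
  if (aa[k] != "*") {
    stop(sprintf("CDS must end with a stop codon; codon %d is %s (%s)",
                 k, codons[k], aa[k]), call. = FALSE)
  }
  internal <- which(aa[-k] == "*")
  if (length(internal) > 0L) {
    stop(sprintf("internal stop codon %s at codon %d", codons[internal[1L]],
                 internal[1L]), call. = FALSE)
  }
  structure(seq, class = "cds", codon_count = k)
}

#' @export
print.cds <- function(x, ...) {
  k <- attr(x, "codon_count")
  cat(sprintf("<cds> %d nt, %d codons (%d residues + stop)\n",
              nchar(x), k, k - 1L))
  cat(if (nchar(x) > 60L) paste0(substr(x, 1L, 57L), "...") else x, "\n")
  invisible(x)
}

.codons_of <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS to its protein
#'
#' Translates codon by codon under the standard code and drops the terminal
#' stop, so the B2M fixture yields its 119-residue protein.
#'
#' @param cds A validated [validate_cds()] object, or a string to validate.
#' @return Single character string of one-letter symbols.
#' @examples
#' translate_cds("ATGTGCTAA")  # "MC"
#' @export
translate_cds <- function(cds) {
  cds <- validate_cds(cds)
  aa <- translate_codon(.codons_of(cds))
  paste(aa[-length(aa)], collapse = "")
}

#' Residue composition of a protein
#'
#' Per-symbol and per-group counts of a protein sequence, optionally counting
#' the terminal stop as one extra "residue" (so the B2M protein totals 120).
#'
#' @param protein One-letter protein string or character vector of symbols.
#' @param include_stop Add one `"*"` to the tally (the terminal stop codon).
#' @return A tibble with `aa`, `group`, `n`, sorted by descending count.
#' @examples
#' residue_composition(translate_cds(b2m_cds()), include_stop = TRUE)
#' @export
residue_composition <- function(protein, include_stop = FALSE) {
  sym <- .as_symbols(protein)
  if (include_stop) {
    sym <- c(sym, "*")
  }
  tibble::tibble(aa = sym, group = residue_group(sym)) |>
    dplyr::count(.data$aa, .data$group, sort = TRUE)
}

#' Positions of a residue in a protein
#'
#' All 1-based positions at which `symbol` occurs (the initiator Met counts
#' as position 1). In the B2M protein the two disulfide-bonded cysteines sit
#' at positions 45 and 100.
#'
#' @param protein One-letter protein string or character vector of symbols.
#' @param symbol A single one-letter symbol.
#' @return Sorted integer vector (empty if the symbol is absent).
#' @examples
#' find_residue_positions(translate_cds(b2m_cds()), "C")  # 45, 100
#' @export
find_residue_positions <- function(protein, symbol) {
  sym <- .as_symbols(protein)
  stopifnot(length(symbol) == 1L)
  residue_group(symbol)  # validates
  which(sym == symbol)
}

.as_symbols <- function(protein) {
  sym <- if (length(protein) == 1L && nchar(protein) != 1L) {
    strsplit(protein, "")[[1]]
  } else {
    protein
  }
  residue_group(sym)  # validates symbols
  sym
}
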