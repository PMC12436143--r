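# Standard genetic code (NCBI translation table 1) and the five-way
# physicochemical grouping of the amino acids. The code table is shipped as a
# plain-text data file so it can be inspected and diffed; it is validated on
# first load and cached for the session.

.snpsat_env <- new.env(parent = emptyenv())

#' Amino-acid group labels
#'
#' The five physicochemical groups partitioning the 20 standard amino acids,
#' plus the `STOP` label for the stop sentinel:
#' `POSITIVE` (Arg, His, Lys), `NEGATIVE` (Asp, Glu), `POLAR` (Ser, Thr, Asn,
#' Gln), `SPECIAL` (Cys, Gly, Pro), `HYDROPHOBIC` (Ala, Val, Ile, Leu, Met,
#' Phe, Tyr, Trp).
#'
#' @format A character vector of the six group labels, in display order.
#' @export
residue_groups <- c("POSITIVE", "NEGATIVE", "POLAR", "SPECIAL",
                    "HYDROPHOBIC", "STOP")

#' The standard genetic code as a tibble
#'
#' Returns the standard codon table (NCBI translation table 1): all 64 codons
#' with their one-letter symbol (`"*"` for the three stop codons), three-letter
#' name, and physicochemical group. Loaded once per session from the packaged
#' plain-text table and validated: 64 codons, 61 sense + 3 stops (TAA, TAG,
#' TGA), every amino acid represented, ATG = Met.
#'
#' @return A tibble with columns `codon`, `aa`, `aa3`, `group`.
#' @examples
#' genetic_code()
#' @export
genetic_code <- function() {
  if (!is.null(.snpsat_env$code)) {
    return(.snpsat_env$code)
  }
  path <- system.file("extdata", "genetic_code.tsv", package = "snpsat",
                      mustWork = TRUE)
  code <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  stopifnot(
    identical(names(code), c("codon", "aa", "aa3", "group")),
    nrow(code) == 64L,
    !anyDuplicated(code$codon),
    sum(code$aa == "*") == 3L,
    setequal(code$codon[code$aa == "*"], c("TAA", "TAG", "TGA")),
    setequal(code$aa[code$aa != "*"], strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
    code$aa[code$codon == "ATG"] == "M",
    all(code$group %in% residue_groups)
  )
  .snpsat_env$code <- code
  code
}

# fast codon -> symbol and symbol -> group lookups
.codon_map <- function() {
  code <- genetic_code()
  stats::setNames(code$aa, code$codon)
}

.group_map <- function() {
  code <- genetic_code()
  map <- code |>
    dplyr::distinct(.data$aa, .data$group)
  stats::setNames(map$group, map$aa)
}

.normalize_bases <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in %s at position %d (alphabet A,C,G,T/U)",
                 substr(x[i], bad[i], bad[i]), what, bad[i]), call. = FALSE)
  }
  x
}

#' Translate codons under the standard genetic code
#'
#' Vectorised codon translation. Case-insensitive; RNA input (U) is accepted
#' and read as T. Ambiguity codes are rejected, not expanded.
#'
#' @param codon Character vector of nucleotide triplets.
#' @return Character vector of one-letter symbols, `"*"` for stop codons.
#' @examples
#' translate_codon(c("ATG", "TAA", "tgc", "AUG"))
#' @export
translate_codon <- function(codon) {
  if (any(nchar(codon) != 3L)) {
    stop("codons must be exactly 3 characters", call. = FALSE)
  }
  codon <- .normalize_bases(codon, what = "codon")
  unname(.codon_map()[codon])
}

#' Physicochemical group of a residue symbol
#'
#' Maps one-letter amino-acid symbols (and the `"*"` stop sentinel) to their
#' group label. Total over the 21 valid symbols; anything else is an error.
#'
#' @param symbol Character vector of one-letter symbols or `"*"`.
#' @return Character vector of group labels (see [residue_groups]).
#' @examples
#' residue_group(c("C", "M", "K", "*"))
#' @export
residue_group <- function(symbol) {
  map <- .group_map()
  bad <- setdiff(unique(symbol), names(map))
  if (length(bad) > 0L) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[symbol])
}

#' Codon-table accounting
#'
#' Counts how many of the 64 codons encode each amino acid (or the stop
#' signal), or each physicochemical group. Under the standard code the
#' per-symbol counts follow the familiar 1/2/3/4/6 pattern and the per-group
#' counts are POSITIVE 10, NEGATIVE 4, POLAR 14, SPECIAL 10, HYDROPHOBIC 23,
#' STOP 3.
#'
#' @param by Count per amino-acid symbol (`"aa"`, default) or per group
#'   (`"group"`).
#' @return A tibble with the grouping column and `n_codons`, summing to 64.
#' @examples
#' codon_counts()
#' codon_counts(by = "group")
#' @export
codon_counts <- function(by = c("aa", "group")) {
  by <- match.arg(by)
  genetic_code() |>
    dplyr::count(.data[[by]], name = "n_codons") |>
    dplyr::arrange(dplyr::desc(.data$n_codons), .data[[by]])
}
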