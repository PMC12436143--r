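# Amino-acid chemical-dissimilarity scoring. The packaged matrix is a
# synthetic reconstruction of Sneath's dissimilarity index (see the methods
# vignette): the published anchor values are exact, the remaining cells are
# rebuilt from physicochemical property distances on the published 5-43 scale.

#' Read an amino-acid dissimilarity matrix
#'
#' Parses a whitespace/tab-delimited 20x20 matrix with one-letter amino-acid
#' row and column labels. Lower-triangular files are accepted and mirrored.
#' The result is validated: all 20 amino acids present, symmetric, zero
#' diagonal, off-diagonal integers in \[5, 43\]. Any violation is a load error.
#'
#' @param path Path to the matrix file. A header row of one-letter codes,
#'   then 20 labelled rows of integer cells.
#' @return A 20x20 symmetric integer matrix with dimnames, class
#'   `"sneath_matrix"`.
#' @seealso [sneath_matrix()] for the packaged default.
#' @export
read_sneath_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("matrix file not found: ", path, call. = FALSE)
  }
  # tab-delimited files may carry empty upper-triangle cells; whitespace
  # delimiting would silently collapse them
  sep <- if (any(grepl("\t", readLines(path, n = 2L, warn = FALSE)))) "\t" else ""
  tab <- utils::read.table(path, header = TRUE, row.names = 1L, sep = sep,
                           check.names = FALSE, fill = TRUE)
  m <- as.matrix(tab)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(rownames(m), aas) || !setequal(colnames(m), aas)) {
    missing <- setdiff(aas, intersect(rownames(m), colnames(m)))
    stop("matrix must be labelled with the 20 amino acids; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- m[aas, aas]
  mode(m) <- "numeric"
  # mirror a lower- (or upper-) triangular file
  m[is.na(m)] <- t(m)[is.na(m)]
  if (anyNA(m)) {
    stop("matrix has missing cells that are not mirrored by the transpose",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m)))) {
    idx <- which(m != t(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix is asymmetric at (%s, %s): %g vs %g",
                 aas[idx[1L]], aas[idx[2L]], m[idx[1L], idx[2L]],
                 m[idx[2L], idx[1L]]), call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop("matrix diagonal must be 0 (identical residues)", call. = FALSE)
  }
  off <- m[row(m) != col(m)]
  if (any(off < 5 | off > 43)) {
    stop("off-diagonal dissimilarities must lie in [5, 43]; found ",
         paste(range(off), collapse = "-"), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  class(m) <- c("sneath_matrix", class(m))
  m
}

#' The packaged dissimilarity matrix
#'
#' Loads (once per session) the packaged synthetic Sneath-style matrix and
#' asserts its published anchor values: Leu-Ile 5 (the smallest possible
#' change), Pro-Glu and Pro-Arg 43 (the largest), Asp-Asn 14, Ala-Pro 16.
#' A mistranscribed file fails fast here.
#'
#' @return A `sneath_matrix` (see [read_sneath_matrix()]).
#' @examples
#' m <- sneath_matrix()
#' m["L", "I"]
#' @export
sneath_matrix <- function() {
  if (!is.null(.snpsat_env$sneath)) {
    return(.snpsat_env$sneath)
  }
  path <- system.file("extdata", "sneath_synthetic.tsv", package = "snpsat",
                      mustWork = TRUE)
  m <- read_sneath_matrix(path)
  stopifnot(
    m["L", "I"] == 5L,
    m["P", "E"] == 43L,
    m["P", "R"] == 43L,
    m["D", "N"] == 14L,
    m["A", "P"] == 16L
  )
  .snpsat_env$sneath <- m
  m
}

#' Dissimilarity score for a substitution
#'
#' Extended scoring used throughout the saturation analysis: 0 when the
#' residue is unchanged (including stop retained as stop), 100 when the
#' substitution creates a stop codon, `stop_loss_score` when a stop codon is
#' lost (read-through), and the matrix value in \[5, 43\] for a genuine
#' amino-acid replacement. Vectorised over pairs.
#'
#' @param original,variant One-letter symbols or `"*"` for stop.
#' @param matrix A `sneath_matrix`; defaults to the packaged one.
#' @param stop_loss_score Score assigned when the original symbol is a stop
#'   and the variant is an amino acid. Defaults to 100: disrupting
#'   termination is treated as severely as truncation.
#' @return Integer vector of scores in `{0} U [5, 43] U {100}` (assuming
#'   `stop_loss_score` in that set).
#' @examples
#' substitution_score("A", "A")  # 0: no change
#' substitution_score("C", "*")  # 100: stop gained
#' substitution_score("L", "I")  # 5: most conservative replacement
#' @export
substitution_score <- function(original, variant, matrix = sneath_matrix(),
                               stop_loss_score = 100L) {
  valid <- c(rownames(matrix), "*")
  bad <- setdiff(unique(c(original, variant)), valid)
  if (length(bad) > 0L) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(original), length(variant))
  original <- rep_len(original, n)
  variant <- rep_len(variant, n)
  score <- integer(n)
  same <- original == variant
  gain <- !same & variant == "*"
  loss <- !same & original == "*"
  sub <- !same & !gain & !loss
  score[gain] <- 100L
  score[loss] <- as.integer(stop_loss_score)
  score[sub] <- matrix[cbind(original[sub], variant[sub])]
  score
}
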