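# Independent brute-force oracle for the saturation engine. Deliberately
# avoids the package's code table and enumeration: each variant rebuilds the
# FULL mutated sequence, re-translates it entirely with Biostrings'
# GENETIC_CODE, and diffs the translation products. Groups are redeclared
# here from scratch.

oracle_groups <- c(
  R = "POSITIVE", H = "POSITIVE", K = "POSITIVE",
  D = "NEGATIVE", E = "NEGATIVE",
  S = "POLAR", T = "POLAR", N = "POLAR", Q = "POLAR",
  C = "SPECIAL", G = "SPECIAL", P = "SPECIAL",
  A = "HYDROPHOBIC", V = "HYDROPHOBIC", I = "HYDROPHOBIC", L = "HYDROPHOBIC",
  M = "HYDROPHOBIC", F = "HYDROPHOBIC", Y = "HYDROPHOBIC", W = "HYDROPHOBIC",
  "*" = "STOP"
)

oracle_translate <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  unname(Biostrings::GENETIC_CODE[codons])
}

# all single-base variants of `seq`, full-sequence re-translation, ordered by
# position then alternate base
oracle_enumerate <- function(seq) {
  seq <- as.character(seq)
  n <- nchar(seq)
  orig_aa_full <- oracle_translate(seq)
  rows <- list()
  for (i in seq_len(n)) {
    ref <- substr(seq, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mutated <- seq
      substr(mutated, i, i) <- alt
      var_aa_full <- oracle_translate(mutated)
      diff <- which(orig_aa_full != var_aa_full)
      ci <- (i - 1L) %/% 3L + 1L
      o <- orig_aa_full[ci]
      v <- var_aa_full[ci]
      stopifnot(length(diff) <= 1L, all(diff == ci))
      cons <- if (o == "*" && v == "*") "stop_retained"
      else if (o == v) "synonymous"
      else if (v == "*") "nonsense"
      else if (o == "*") "stop_loss"
      else if (oracle_groups[[o]] == oracle_groups[[v]]) "same_group_missense"
      else "cross_group_missense"
      rows[[length(rows) + 1L]] <- data.frame(
        nt_position = i, codon_index = ci,
        offset_in_codon = (i - 1L) %% 3L + 1L,
        ref_base = ref, alt_base = alt,
        original_aa = o, variant_aa = v, consequence = cons,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# named integer vector from a 1-d table, for attribute-free comparisons
tab2vec <- function(t) stats::setNames(as.integer(t), names(t))
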