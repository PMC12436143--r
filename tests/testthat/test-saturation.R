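test_that("consequence classification follows the six-way contract", {
  expect_equal(as.character(classify_consequence(
    c("C", "*", "M", "D", "A", "*"),
    c("*", "Q", "I", "N", "A", "*"))),
    c("nonsense", "stop_loss", "same_group_missense", "cross_group_missense",
      "synonymous", "stop_retained"))
  expect_error(classify_consequence("A", "Z"), "unknown residue")
})

test_that("each codon yields exactly its 9 single-base variants", {
  rec <- enumerate_snps("ATGTAA")
  expect_equal(nrow(rec), 18L)
  # set equality with all single-position single-letter edits of ATG
  atg <- rec[rec$codon_index == 1L, ]
  expected <- sort(c("CTG", "GTG", "TTG", "AAG", "ACG", "AGG",
                     "ATA", "ATC", "ATT"))
  expect_equal(sort(atg$variant_codon), expected)
  want <- c(I = 3L, K = 1L, L = 2L, R = 1L, T = 1L, V = 1L)
  expect_equal(tab2vec(table(atg$variant_aa))[names(want)], want)
  expect_true(all(rec$ref_base != rec$alt_base))
  # variant codon differs from original at exactly one position
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, rec$original_codon, rec$variant_codon)
  expect_true(all(ndiff == 1L))
  expect_equal(rec$nt_position, 3L * (rec$codon_index - 1L) + rec$offset_in_codon)
})

test_that("records are ordered by position then alternate base", {
  rec <- enumerate_snps(generate_random_cds(10, seed = 42))
  expect_equal(order(rec$nt_position, rec$alt_base), seq_len(nrow(rec)))
})

test_that("enumeration agrees record-for-record with full-sequence re-translation", {
  for (seed in 1:4) {
    n_codons <- c(5L, 12L, 21L, 30L)[seed]
    cds <- generate_random_cds(n_codons, seed = seed)
    got <- enumerate_snps(cds)
    want <- oracle_enumerate(cds)
    expect_equal(nrow(got), 3L * nchar(cds))
    for (col in c("nt_position", "codon_index", "offset_in_codon",
                  "ref_base", "alt_base", "original_aa", "variant_aa")) {
      expect_equal(got[[col]], want[[col]], label = paste("column", col))
    }
    expect_equal(as.character(got$consequence), want$consequence)
    # six-way classes partition 3L
    expect_equal(sum(table(got$consequence)), 3L * nchar(cds))
  }
})

test_that("scores obey the class-wise constraints on random sequences", {
  for (seed in 5:7) {
    rec <- enumerate_snps(generate_random_cds(25, seed = seed))
    expect_true(all(rec$sneath_score[rec$consequence == "synonymous"] == 0L))
    expect_true(all(rec$sneath_score[rec$consequence == "stop_retained"] == 0L))
    expect_true(all(rec$sneath_score[rec$consequence == "nonsense"] == 100L))
    mis <- rec$consequence %in% c("same_group_missense", "cross_group_missense")
    expect_true(all(rec$sneath_score[mis] >= 5L & rec$sneath_score[mis] <= 43L))
    expect_true(all(rec$sneath_score %in% c(0L, 5:43, 100L)))
  }
})

test_that("the engine is sense-strand only", {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b2m_cds())))
  expect_error(validate_cds(rc))
})
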