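test_that("partition of a minimal CDS matches hand enumeration", {
  # ATGTAA: ATG's 9 variants are I/I/I, L/L, V (hydrophobic, same group) and
  # K, T, R (cross); TAA's 9 are 2 stop-retained + 7 stop-loss.
  rec <- enumerate_snps("ATGTAA")
  expect_equal(as.vector(table(rec$consequence)[consequence_classes]),
               c(0L, 6L, 3L, 0L, 2L, 7L))
  part <- consequence_partition(rec)
  expect_equal(stats::setNames(part$n, as.character(part$bucket)),
               c(no_change = 0L, same_group = 6L, different_group = 12L,
                 stop_gain = 0L))
  expect_equal(sum(part$n), 18L)
  part2 <- consequence_partition(rec, stop_fold = "no_change")
  expect_equal(part2$n[part2$bucket == "no_change"], 2L)
  part3 <- consequence_partition(rec, stop_fold = "stop_gain")
  expect_equal(part3$n[part3$bucket == "stop_gain"], 2L)
  expect_error(consequence_partition(rec[0, ]), "no records")
})

test_that("partition percentages are half-up one-decimal and sum to ~100", {
  for (seed in 1:3) {
    rec <- enumerate_snps(generate_random_cds(20, seed = seed))
    part <- consequence_partition(rec)
    expect_equal(sum(part$n), nrow(rec))
    expect_equal(part$percent, round_half_up(100 * part$n / nrow(rec), 1))
    expect_lt(abs(sum(part$percent) - 100), 0.21)
  }
  expect_equal(round_half_up(c(22.15, 5.25, 47.24), 1), c(22.2, 5.3, 47.2))
})

test_that("strict and charge-merged similarity differ only on charged pairs", {
  rec <- enumerate_snps(b2m_cds())
  strict <- consequence_partition(rec, similarity = "strict")
  merged <- consequence_partition(rec, similarity = "charged_merged")
  charged <- c("POSITIVE", "NEGATIVE")
  cross_charged <- sum(rec$consequence == "cross_group_missense" &
                         rec$original_group %in% charged &
                         rec$variant_group %in% charged)
  expect_equal(merged$n[merged$bucket == "same_group"],
               strict$n[strict$bucket == "same_group"] + cross_charged)
  expect_equal(sum(strict$n), sum(merged$n))
})

test_that("per-residue tables conserve totals and recompose the partition", {
  rec <- enumerate_snps(b2m_cds())
  symbols <- unique(rec$original_aa)
  totals <- vapply(symbols, function(s) sum(substitution_table(rec, s)$n),
                   integer(1))
  expect_equal(sum(totals), nrow(rec))
  # per-symbol totals are 9 x codon occurrences in the CDS (stop included)
  occ <- table(c(strsplit(b2m_protein(), "")[[1]], "*"))
  expect_equal(totals[names(occ)], 9L * as.vector(occ), ignore_attr = TRUE)
  # group table equals residue table composed with the grouping
  for (s in c("M", "C", "*")) {
    tab <- substitution_table(rec, s)
    grp <- group_substitution_table(rec, s)
    expect_equal(sum(grp$n), sum(tab$n))
    agg <- tapply(tab$n, tab$variant_group, sum)
    expect_equal(grp$n, as.integer(agg[grp$variant_group]))
  }
  # re-classifying the tallied pairs reproduces the direct partition
  pairs <- dplyr::count(rec, original_aa, variant_aa)
  pairs$consequence <- classify_consequence(pairs$original_aa, pairs$variant_aa)
  direct <- table(rec$consequence)
  via_pairs <- tapply(pairs$n, pairs$consequence, sum, default = 0L)
  expect_equal(as.vector(via_pairs[names(direct)]), as.vector(direct))
  # absent symbol gives an empty table, not an error
  expect_equal(nrow(substitution_table(enumerate_snps("ATGTAA"), "W")), 0L)
})

test_that("frequency shift columns are consistent with composition and sum to 100", {
  cds <- validate_cds(b2m_cds())
  rec <- enumerate_snps(cds)
  shift <- frequency_shift(cds, rec)
  expect_equal(sum(shift$pct_original), 100)
  expect_equal(sum(shift$pct_variant), 100)
  comp <- residue_composition(translate_cds(cds), include_stop = TRUE)
  expect_equal(
    stats::setNames(shift$n_original, shift$aa)[comp$aa],
    stats::setNames(comp$n, comp$aa)
  )
  expect_equal(shift$pct_original[shift$aa == "W"], 100 * 2 / 120)
  # glutamic acid becomes rarer in the variant pool than in the original
  expect_lt(shift$pct_variant[shift$aa == "E"], shift$pct_original[shift$aa == "E"])
  expect_error(frequency_shift(cds, rec[-1, ]), "do not match")
})

test_that("mean score per original residue equals hand sums on a toy CDS", {
  # single sense codon TGC (Cys): variants AGC/CGC/GGC/TAC/TCC/TTC/TGA/TGG/TGT
  rec <- enumerate_snps("ATGTGCTAA")
  m <- sneath_matrix()
  cys <- rec[rec$original_aa == "C", ]
  hand <- (m["C", "S"] * 2 + m["C", "R"] + m["C", "G"] + m["C", "Y"] +
             m["C", "F"] + m["C", "W"] + 100 + 0) / 9
  means <- mean_sneath_by_original(rec)
  expect_equal(means$mean_score[means$original_aa == "C"], hand)
  expect_equal(means$n[means$original_aa == "C"], 9L)
})

test_that("cysteine's mean in B2M reflects its two stop-gain variants", {
  rec <- enumerate_snps(b2m_cds())
  cys <- rec[rec$original_aa == "C", ]
  expect_equal(nrow(cys), 18L)
  expect_equal(sum(cys$sneath_score == 100L), 2L)
  means <- mean_sneath_by_original(rec)
  expect_equal(means$n[means$original_aa == "C"], 18L)
})
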