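---
title: "In silico SNP saturation of a coding sequence: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico SNP saturation of a coding sequence: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsat)
```

## The procedure

snpsat performs exhaustive in-silico saturation mutagenesis of a single
protein-coding sequence (CDS). Given a validated CDS of L nucleotides — ATG
start, in-frame terminal stop, no internal stop, alphabet A/C/G/T (U read as
T) — the engine generates every possible single-nucleotide substitution: 3
alternatives at each position, 9 per codon, 3L in total. Each variant codon
is translated against the original reading frame (one base is mutated at a
time; compound variants are out of scope) and the substitution is classified
and scored. Because the enumeration is exhaustive and the genetic code is
fixed, every result in this package is a deterministic function of the input
sequence; there is no sampling anywhere in the analysis itself.

The worked example throughout is beta-2-microglobulin (B2M), the smallest
immunoglobulin-domain protein: a 360-nt mature CDS encoding 119 residues
plus the terminal stop, with a single disulfide bond between Cys45 and
Cys100. Both sequences ship as plain-text FASTA fixtures (`b2m_cds()`,
`b2m_protein()`).

## Consequence classification

Every variant is first classified six ways, on the (original, variant)
symbol pair:

* `synonymous` — same amino acid;
* `same_group_missense` — different amino acids of one physicochemical group;
* `cross_group_missense` — different amino acids of different groups;
* `nonsense` — a sense codon becomes a stop codon (truncation);
* `stop_retained` — the terminal stop codon mutates to another stop codon;
* `stop_loss` — the terminal stop codon becomes a sense codon
  (read-through; the elongated downstream sequence is not modelled).

The grouping is the five-way partition of the 20 amino acids used throughout
the package: POSITIVE (Arg, His, Lys), NEGATIVE (Asp, Glu), POLAR (Ser, Thr,
Asn, Gln), SPECIAL (Cys, Gly, Pro), HYDROPHOBIC (Ala, Val, Ile, Leu, Met,
Phe, Tyr, Trp). Under the standard code these groups are encoded by 10, 4,
14, 10 and 23 codons respectively (plus 3 stop codons), which
`codon_counts()` verifies by brute force over all 64 codons.

## The headline four-way partition

`consequence_partition()` collapses the six classes into the four buckets a
reader of a saturation scan usually wants: *no change*, *similar-group
substitution*, *different-group substitution*, *stop gain*. Two conventions
are configurable, and their defaults deserve explanation because the design
was genuinely open:

**Similarity rule.** By default (`similarity = "charged_merged"`) a
replacement of one charged residue by another — across the positive/negative
divide, e.g. Lys by Glu — is counted in the *similar group* bucket: both
side chains are ionisable and the substitution preserves the charged
character of the site, if not its sign. The strict five-way rule
(`similarity = "strict"`), under which only within-group replacements are
similar, is a switch away; the six-way records are unaffected either way.
For the B2M scan the two rules differ by 28 variants (274 vs 246 in the
similar bucket).

**Terminal-stop folding.** The 9 variants of the terminal stop codon are
neither ordinary missense nor ordinary nonsense. The default
(`stop_fold = "different_group"`) keeps the *no change* and *stop gain*
buckets restricted to sense-codon events — so they read directly as
"synonymous" and "truncating" — and reports all terminal-stop variants
(2 stop-retained + 7 stop-loss for a TAA terminus) in the residual
*different group* bucket, since disturbing termination changes the product
more than any single residue swap. Folding stop-retained variants with
*no change* (they leave the protein unchanged) or with *stop gain* (the
variant codon is a stop) are both available via `stop_fold`.

Percentages are rounded half-up to one decimal, the convention of printed
tables. For B2M the defaults give 239 (22.1%) no change, 274 (25.4%)
similar group, 57 (5.3%) stop gain and 510 (47.2%) different group — hence
47.5% of variants with no or minimal effect versus 52.5% with a
potentially large one.

## Dissimilarity scoring

Amino-acid replacements are scored with Sneath's chemical dissimilarity
index, an integer scale on which 5 (Leu–Ile) is the most conservative
possible replacement and 43 (Pro–Glu, Pro–Arg) the most disruptive. The
scan extends the scale at both ends: 0 when the residue is unchanged
(synonymous and stop-retained variants) and 100 when a stop codon is
gained, representing truncation as categorically worse than any
substitution. Stop-loss variants default to 100 as well — read-through
disrupts termination as severely as truncation — but the score is exposed
as `stop_loss_score` (valid values 0, 5–43, or 100) so per-residue averages
can be recomputed under a milder reading. Scores are integers throughout;
no interpolation or normalisation is applied.

**The packaged matrix is a synthetic reconstruction.** The original
published table is not redistributed here. The shipped file
(`inst/extdata/sneath_synthetic.tsv`) rebuilds the 20×20 table from
z-scored physicochemical properties (Kyte–Doolittle hydropathy; Grantham
polarity, volume and composition), mapping Euclidean property distances
affinely onto the 5–43 scale, and then pins the published anchor values
exactly: Leu–Ile 5 (the unique minimum), Pro–Glu 43 and Pro–Arg 43 (the
maxima), Asp–Asn 14, Ala–Pro 16. Loading validates symmetry, the zero
diagonal, the 5–43 range and the anchors, so a mistranscribed file fails
fast. The consequence classification and all count-based summaries are
independent of the matrix; per-pair scores other than the anchors, and
therefore the per-residue mean scores, are property-based approximations
and should be read as such. `read_sneath_matrix()` accepts a user-supplied
square or lower-triangular table for anyone holding the original values.

## Summaries

From the per-variant records the package derives: per-original-residue
substitution tables (`substitution_table()`, totals are 9 × codon
occurrences), their group-level aggregation, the frequency shift of each
residue between the original translation product (per codon, stop included:
120 positions for B2M) and the variant pool (per variant: 1080 for B2M),
and the mean dissimilarity score per original residue
(`mean_sneath_by_original()`), whose extremes in B2M are driven by
stop-gain-prone codons (Trp, Tyr, Cys). Each summary conserves its input:
partition counts sum to 3L, per-residue tables sum to the record count, and
both frequency columns sum to 100%.

## The random-CDS generator

`generate_random_cds(n_codons, seed)` exists for property testing, not for
modelling biology. It draws internal codons uniformly from the 61 sense
codons between a fixed ATG start and a uniformly chosen stop, so a valid
CDS is produced by construction (no rejection sampling) and the result is
reproducible for a fixed seed. It emulates only the structural contract of
a CDS — start, frame, stop, no internal stop. It does not emulate codon
usage bias, GC content, or any homology structure of real genes, so tests
passing on generated sequences demonstrate the engine's bookkeeping
(enumeration completeness, classification consistency, conservation laws)
rather than anything about real coding sequences. The test suite runs the
engine against an independent brute-force oracle — one that rebuilds each
full mutated sequence and re-translates it entirely with Biostrings — on
seeded random CDSs of up to 30 codons, and checks the B2M fixture
end-to-end; these sizes keep the default suite in the order of seconds
while exercising every code path.

## Degenerate inputs and numerical choices

* Validation errors are specific and position-reporting (bad character,
  frame, missing start/stop, internal stop); a reverse-complement input
  fails validation — the engine is sense-strand only.
* The minimal accepted CDS is ATG + stop (two codons, 18 variants).
* Record order is fixed (position-major, then alternate base A<C<G<T), so
  written tables are byte-reproducible.
* Ambiguity codes are rejected, never expanded; only the standard genetic
  code is supported, and alternative tables are rejected rather than
  silently substituted.
* Percentages use half-up rounding (`round_half_up()`), not banker's
  rounding, to match printed-table conventions.

## Known limitations

Single-nucleotide substitutions only: no indels, multi-nucleotide variants,
splice or genomic (multi-exon) coordinates, population frequencies, or
annotation against variant databases. Classification is at the primary
structure level; effects on secondary, tertiary or quaternary structure —
including the disulfide bond whose cysteines the scan merely flags — are
outside the model. The read-through product of a stop-loss variant is not
extended past the original terminus.
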