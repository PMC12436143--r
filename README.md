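# snpsat

Exhaustive in-silico SNP saturation analysis of a protein-coding sequence.

Every position of a coding sequence (CDS) can mutate to three alternative
bases, so an L-nt CDS has exactly 3L possible single-nucleotide variants.
`snpsat` enumerates all of them, translates each variant codon in the
original frame, classifies the consequence — synonymous, same-group or
cross-group missense under a five-way physicochemical grouping of the amino
acids (positive / negative / polar / special / hydrophobic), nonsense,
stop-retained, stop-loss — and scores each substitution with a Sneath-style
chemical-dissimilarity index on the 5–43 scale, extended with 0 for no
change and 100 for stop-codon involvement. It is aimed at anyone asking,
for a single gene of interest, *what fraction of possible point mutations
is silent, conservative, disruptive, or truncating* — the package ships the
mature beta-2-microglobulin (B2M) CDS (360 nt, 119 residues, disulfide
Cys45–Cys100) as its worked example.

All results are tidy tibbles that chain with the pipe; `saturate()` returns
an object with broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()`.

## Worked example: B2M

```r
library(snpsat)

sat <- saturate(b2m_cds())
sat
#> <snp_saturation> 360 nt CDS, 120 codons, 1080 variants
#>   no_change        239 (22.1%)
#>   same_group       274 (25.4%)
#>   different_group  510 (47.2%)
#>   stop_gain         57 (5.3%)
```

Of the 1080 possible variants, 239 (22.1%) leave the residue unchanged, 274
(25.4%) replace it by a chemically similar one, 57 (5.3%) create a
premature stop codon, and 510 (47.2%) substitute across chemical groups —
i.e. 47.5% of point mutations have no or minimal primary-structure effect
and 52.5% a potentially large one.

```r
translate_cds(b2m_cds()) |> find_residue_positions("C")
#> [1]  45 100

tidy(sat) |> substitution_table("C")
#> # A tibble: 8 × 3
#>   variant_aa variant_group     n
#>   <chr>      <chr>         <int>
#> 1 S          POLAR             4
#> 2 *          STOP              2
#> 3 C          SPECIAL           2
#> 4 F          HYDROPHOBIC       2
#> 5 G          SPECIAL           2
#> 6 R          POSITIVE          2
#> 7 W          HYDROPHOBIC       2
#> 8 Y          HYDROPHOBIC       2
```

The 18 variants of the two disulfide-bond cysteines include two nonsense
events (score 100) and two synonymous ones; the per-residue mean scores
(`mean_sneath_by_original()`) are highest for Trp, Tyr and Cys precisely
because their codons mutate readily into stop codons.

`substitution_score()` exposes the scoring directly: Leu→Ile is 5 (the most
conservative replacement on the scale), Pro→Glu and Pro→Arg are 43 (the
most disruptive), any stop gain is 100, no change is 0. The packaged matrix
is a synthetic reconstruction (published anchor values exact, remaining
cells rebuilt from physicochemical properties — see the methods vignette);
`read_sneath_matrix()` loads a user-supplied table instead.

A thin command-line front end mirrors the R interface:

```sh
Rscript inst/cli/snpsat.R --fasta inst/extdata/b2m_cds.fasta \
  --out out/ --residues 'M,C,*'
```

writing the per-variant table (one row per SNP: position, codon, bases,
residues, groups, consequence, score), the partition, frequency-shift and
mean-score summaries, and per-residue substitution tables as TSV.

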