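Package: snpsat
Title: Exhaustive In Silico SNP Saturation Analysis of Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates every possible single-nucleotide variant of a
    protein-coding sequence, classifies each resulting amino-acid
    substitution by consequence (synonymous, same-group or cross-group
    missense, nonsense, stop-retained, stop-loss) under a five-way
    physicochemical grouping of the amino acids, and scores substitutions
    with a Sneath-style chemical-dissimilarity index extended with 0 for
    no change and 100 for stop-codon involvement. Ships the mature
    beta-2-microglobulin (B2M) coding sequence as a worked example and
    reproduces its published saturation summaries. Results are tidy
    tibbles that chain with the pipe; ggplot2 autoplot methods and
    broom-style tidiers are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
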