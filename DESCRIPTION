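Package: ecodiverge
Title: Genetic and Transcriptomic Divergence Between Crop Ecotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene population-genetic and transcriptomic divergence
    analysis for two-ecotype crop panels: nucleotide diversity, Hudson
    F_ST and D_xy scans with highly-differentiated-gene and
    polymorphism/divergence sweep calls; expression diversity, expression
    Q_ST with permutation tests and drought-responsive gene calling; a
    rank-based detector for transcriptionally selected genes with a
    mixed-model between-individual variance cutoff and an expression
    selection index; promoter scanning for cis-element-altering SNPs
    under IUPAC motif libraries with haplotype-level expression
    comparisons; an unsigned weighted co-expression network (topological
    overlap, dynamic tree cut, module eigengenes, hub genes,
    module-trait correlations); and trait Q_ST versus neutral F_ST,
    trait-correlated gene sets, Fisher enrichment and drought-tolerance
    trade-off statistics. Includes a fully seeded synthetic-data
    generator that plants every structure the analyses assume, so the
    whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
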