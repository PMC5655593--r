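Package: omegapair
Title: Genome-Pair dN/dS, Coding Density and ANI Analysis with a Codon
    Evolution Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the efficiency of purifying selection across cohorts
    of closely related genome pairs. Detects orthologs by bidirectional best
    hit with within-genome paralog collapsing, back-threads protein
    alignments to codon alignments, estimates dN/dS by the Nei-Gojobori
    (1986) and Yang-Nielsen (2000) counting methods with saturation filters
    and a coding-capacity retention rule, computes fragment-based average
    nucleotide identity and coding density, and relates per-pair mean dN/dS
    to genome size by Spearman rank correlation. Includes a GY94 codon
    substitution simulator that generates genome-pair cohorts with known
    omega, kappa and divergence so every pipeline stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
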