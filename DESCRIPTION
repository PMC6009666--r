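Package: foxdiv
Title: Cooperative FOXA1 Homodimerization on the Palindromic DIV Element
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of DNA-mediated FOXA1 homodimerization on
    the compact palindromic DIV element. Implements the two-site equilibrium
    cooperative-binding model behind EMSA band quantification (cooperativity
    factor omega and dissociation-constant estimation by quadratic
    ligand-depletion isotherm fitting), construction and genome scanning of
    composite dimer position weight matrices (DIV, CON and spacer-perturbed
    controls) with sensitivity-calibrated thresholds, ChIP-seq peak
    categorization by motif content, two-condition ATAC-seq accessibility
    dynamics classification, and an allele-specific screen of SNPs on the
    motif's shared central TA dinucleotide. A synthetic-data generator
    produces genomes with planted motifs, peaks, accessibility counts, SNP
    tables and noisy titrations with the statistical structure the analysis
    assumes, so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    minpack.lm,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
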