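Package: synoscan
Title: Phenotypic Analysis of Single Synonymous Codon Substitutions in a
    Toxin-Antitoxin Operon
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deep mutational scanning of single synonymous codon
    substitutions in an operon-encoded toxin gene. Converts per-variant
    sequencing read counts from resistant, sensitive and transcriptional
    reporter strains into enrichment scores, degree-of-variation statistics
    and four-class phenotypes; computes codon-usage covariates (relative
    codon usage, CAI, tAI, relative tRNA abundance, wobble-base and
    hydropathy profiles), anti-Shine-Dalgarno sliding-window hybridization
    energies and windowed mRNA minimum-free-energy profiles via the
    ViennaRNA command-line tools, and codon- and residue-level evolutionary
    conservation from user-supplied alignments. Region-stratified summaries
    and significance-masked correlation matrices reproduce the figure-level
    statistics of such screens, and a seeded multinomial simulator with
    known ground truth makes the whole pipeline testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: ViennaRNA (RNAduplex, RNAfold on the PATH)
Config/testthat/edition: 3
biocViews: Software, Sequencing, Genetics, Coverage
RoxygenNote: 7.3.3
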