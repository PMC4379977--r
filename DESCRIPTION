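Package: temark
Title: Transposable-Element Discovery and TE-Based Marker Design
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structure-based discovery of full-length LTR retrotransposons
    (TG..CA termini, target-site duplications, primer-binding site and
    polypurine tract, Copia/Gypsy domain order), homology-based repeat
    annotation and repeat-junction extraction, insertion-time dating from
    LTR-LTR divergence (p, Jukes-Cantor, Kimura two-parameter and
    Nei-Gojobori 1986 synonymous/non-synonymous distances), design of six
    classes of TE-based PCR markers (RBIP, IRAP, RJM, RJJM, ISBP, REMAP)
    with an in-silico PCR uniqueness screen, nested-TE and intron-insertion
    summaries, and marker-based diversity analysis (Jaccard similarity,
    neighbour-joining trees with bootstrap, a no-admixture Bayesian
    clustering Gibbs sampler and Evanno delta-K model choice). A synthetic
    genome generator plants elements with known ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    vegan,
    optparse
biocViews: Annotation, SequenceMatching, Genetics, PopulationGenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
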