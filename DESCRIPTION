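Package: coxcensus
Title: Screening and Biogeography of Potential Carbon Monoxide Oxidizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies potential cox-containing carbon monoxide oxidizers
    (pcox-CO oxidizers) in annotated prokaryotic genome collections and
    characterizes their biogeography. Form I CoxL genes are screened by a
    three-gate procedure (active-site motif, monophyly with a form I
    reference, coxMSL operon structure), genomes are grouped into species
    clusters at 95 percent average nucleotide identity, and marker-gene RPKM
    arithmetic converts read-mapping counts into whole-community and
    operon-based relative abundances. Downstream tools cluster metagenome
    samples by Bray-Curtis composition with subsample-stability selection of
    the number of clusters, extract Spearman co-occurrence networks under a
    false-discovery-rate gate with a pcox-specific edge-retention rule,
    contrast pangenomes of operon-bearing versus coxL-lacking genomes within
    species clusters, and summarize quantitative PCR standard curves and
    copy-density ratios. A synthetic-data generator with planted ground
    truth supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
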