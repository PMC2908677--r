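Package: PufRegulon
Title: Comparative Analysis of PUF-Family RNA-Binding Protein Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of post-transcriptional regulons
    defined by short RNA-binding-protein recognition elements in 3' untranslated
    regions, modelled on the Puf3p regulon of budding yeast. The package scans
    gene-anchored 3' downstream sequences for a configurable 8-nucleotide
    binding-element profile, tests per-window motif enrichment against
    GC-matched random-sequence backgrounds with Fisher's exact test and
    Bonferroni correction, calls target genes by a 3' UTR cutoff, maps targets
    to subcellular-localization categories through ortholog tables and tests
    hypergeometric enrichment, builds cross-species target-conservation
    matrices, compares codon adaptation index (CAI) distributions between gene
    groups and clades, and quantifies co-expression and expression-shift
    association of target genes. A seedable multi-species simulator generates
    complete input bundles with planted motifs, codon-bias shifts, and
    block-correlated expression so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, MotifAnnotation,
    ComparativeGenomics, GeneRegulation
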