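Package: asannot
Title: Junction-Incorporating Multi-Omic Annotation of Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts heterogeneous differential alternative splicing (DAS)
    results (rMATS, SUPPA, spliceR-style isoform pairs, generic TSV) into
    canonical seven-type alternative splicing event records, annotates each
    event with junction-incorporating sequence features spanning DNA
    (conservation, mutation, repeats), RNA (miRNA binding sites,
    nonsense-mediated decay, RNA-binding protein sites, cross-sample exon
    usage) and protein (domains, post-translational modification sites,
    isoform-specific protein-protein interactions, subcellular localization)
    using AS-type-aware region rules, and tests knowledge-based pathway
    over-representation and pairwise feature dependency. Ships a seeded
    synthetic-fixture generator emulating every supported input dialect, a
    command-line interface, and genome-track, interaction-network and
    enrichment bar-plot rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    ggplot2,
    rlang,
    graphics,
    igraph,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
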