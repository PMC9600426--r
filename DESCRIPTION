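Package: SporeTnSeq
Title: Simulation and Analysis of Synthetic Sporulation Tn-Seq Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for transposon insertion sequencing (Tn-seq) screens that
    identify conditionally essential sporulation genes in Bacillus subtilis
    and related endospore formers. Provides a synthetic-data generator that
    emulates saturated mariner-family insertion libraries at TA dinucleotides,
    sporulation followed by heat-kill selection and a germination pooling
    bottleneck, and MmeI-style junction-tag sequencing; an exact-match
    junction-tag mapper producing per-TA-site read tallies; and the screen
    statistics: winsorized library normalization, per-gene fold reduction of
    insertions, Mann-Whitney U underrepresentation tests with exact
    enumeration for small genes, and Benjamini-Hochberg adjustment. Also
    includes sporulation-efficiency arithmetic and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, FunctionalGenomics, Software
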