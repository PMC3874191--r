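Package: replidyn
Title: Genome Replication Dynamics from Deep-Sequencing Copy Number
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures eukaryotic genome replication dynamics from the ratio
    of sequencing read depth between replicating and nonreplicating samples.
    Implements windowed relative copy-number profiles for four experiment
    designs (hydroxyurea origin mapping, synchronous time courses, sort-seq
    and marker frequency analysis), per-window sigmoid fitting with a
    closed-form median replication time (Trep), Fourier low-pass smoothing
    with low-density and chromosome-end exclusions, peak calling and
    origin matching, per-window statistical comparison of profiles, and a
    stochastic origin-firing replication simulator that generates synthetic
    reads for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    minpack.lm,
    withr,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Coverage, DNAReplication, Software
RoxygenNote: 7.3.3
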