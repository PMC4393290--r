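Package: twistflexr
Title: Genome-Wide DNA Twist-Flexibility Profiling and Peak Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-window DNA conformational flexibility profiles from
    genome FASTA as sequence-dependent fluctuations of the helical twist angle
    between consecutive base pairs, calls flexibility peaks with a two-threshold
    rule (a genome-wide mean + k*sd preselection and a fixed peak threshold),
    and analyses their genomic context: intergenic-region orientation classes,
    UTR co-localization, AT tandem-repeat detection, distances to scored
    polyadenylation cleavage sites, and the associated enrichment (Fisher) and
    group-comparison (Welch t) statistics. Includes a synthetic-genome
    generator with ground-truth manifests so every stage is testable offline,
    and a command-line interface over the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    tools,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
SystemRequirements: C++11
Config/testthat/edition: 3
RoxygenNote: 7.3.3
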