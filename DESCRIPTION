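Package: tetraphase
Title: Tetranucleotide-Informed Metagenome Stability Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds metagenome "stability diagrams" from unassembled
    sequencing reads. Canonical tetranucleotide (4-mer) frequency
    signatures and their pairwise ratios are computed per metagenome,
    projected onto two supervised linear-discriminant axes against
    ecosystem classification labels, and overlaid with k-nearest-neighbour
    ecosystem "phase" regions. Gene-annotation counts parsed from GFF3
    files are normalized per billion assembled bases, compared between
    ecosystem groups with Welch's heteroscedastic ANOVA and Games-Howell
    post hoc tests, and ranked by random-forest mean-decrease-in-impurity
    importance. A Markov-chain synthetic-community generator makes every
    pipeline stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    ranger,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
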