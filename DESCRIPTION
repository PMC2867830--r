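Package: refscaf
Title: Reference-Guided Scaffolding, Gap Closing and Validation for
    Bacterial Genome Finishing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Finishes draft bacterial genome assemblies against a closely
    related reference genome. De novo scaffolds are anchored with spaced
    seeds, ordered and oriented along the reference, and the junctions
    between adjacent scaffolds are closed by suffix-prefix overlap merging
    and by splicing sequence from a quality-filtered reference-guided
    consensus built from short-read alignments. Includes in-silico
    restriction digestion with fragment-map comparison, in-silico PCR for
    deletion verification, and a seeded synthetic-data generator (derived
    genomes with insertion-sequence repeats, operon-scale deletions, SNPs
    and short indels; scaffold shredding; paired-end read simulation) with
    truth tables so every stage of the pipeline can be validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Matrix,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Assembly, Alignment, SequenceMatching, Sequencing
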