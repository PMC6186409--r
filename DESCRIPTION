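Package: phenonet
Title: Phenotype-Specific Protein Interaction Networks from Multi-Dataset Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies a phenotype-specific protein-interaction network from
    multiple two-group expression studies. Implements consensus differential
    expression calling across datasets and normalization routes (fold-change
    plus Welch t-test per route, present-call filtering, within- and
    cross-dataset selection rules), EASE-score gene-set over-representation
    with custom backgrounds, pathway-overlap networks built from shared
    differentially expressed genes, core/first-shell interaction network
    assembly from scored interaction tables, and MCODE-style molecular
    complex detection. Ships a seeded synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
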