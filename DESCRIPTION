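Package: recepstruct
Title: Structure-Function Analysis of Engineered Receptor Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies geometric features of predicted receptor-ligand
    complex structures (inter-chain contacts by van der Waals overlap,
    secondary-structure-anchored terminal distances, transmembrane helix
    crossing and exit angles) and relates them to receptor performance
    through a reproducible regression workflow: single-feature fits,
    correlation screens, full and collinearity-reduced linear models
    (variance inflation factor filtering followed by backward elimination),
    one-hot categorical models, and combined models. Includes synthetic
    structure and dataset generators so that every stage of the pipeline is
    testable without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
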