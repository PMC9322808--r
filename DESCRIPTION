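Package: ecbscreen
Title: Evolutionary Chemical Binding Similarity Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening with learned chemical binding
    similarity. Compound pairs whose binding targets are identical or
    evolutionarily related (homologous at a sequence-identity threshold)
    are treated as positives for a similarity-learning classifier; a
    target-specific bootstrap ensemble scores library compounds against
    reference ligands and the maximum pairwise score over references
    becomes the final target-binding score in [0,1]. Includes homology
    graph construction from sequences or identity tables, evolutionarily
    related chemical pair enumeration with negative sampling, a staged
    screening funnel (score cutoff, top-k, expert keep-list), enrichment
    metrics (AUROC, enrichment factor, recall at k), a synthetic
    compound/target world generator with planted fingerprint motifs for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
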