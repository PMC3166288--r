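Package: nolscan
Title: Prediction of Nucleolar Localization Sequences in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window detection of nucleolar localization sequences
    (NoLSs) in proteins, replicating the NoD/clinod prediction pipeline:
    13-residue windows are sparsely encoded over a 12-group reduced
    amino-acid alphabet, scored by a trainable feed-forward neural network,
    and NoLS segments are called where the mean score of 8 consecutive
    windows reaches 0.8. Includes clinod-compatible batch output formats,
    an interval-overlap evaluation framework with the published
    multi-organism NoD benchmark, and a synthetic-data generator of
    basic-residue-rich motifs for training and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
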