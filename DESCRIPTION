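Package: gcnpredict
Title: Transcriptome Prediction and In Silico Perturbation with Gene
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("gcnpredict", "developers", email = "gcnpredict@example.org",
           role = c("aut", "cre"))
Description: Builds gene co-expression networks from RMA-scale expression
    compendia by thresholded pairwise Pearson correlation, attaching an
    ordinary-least-squares affine model to every retained edge in both
    orientations. From the network it selects a compact panel of source
    (marker) genes by greedy maximal coverage within a jump limit, predicts
    the expression of all reachable target genes by composing per-edge
    regressions along enumerated simple paths (single-pass and multi-pass
    modes), and simulates multiplicative gene perturbations
    (over-expression, knockdown, knockout) via two-pass prediction with
    significance classification of affected genes, including expression
    buffer estimation by quadratic fits to ratio sweeps. A seeded
    latent-factor simulator supplies expression matrices with known
    co-expression structure for testing, and a command line interface wires
    the steps into a pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
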