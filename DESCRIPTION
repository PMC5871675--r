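Package: proportionator
Title: Non-Uniform Proportionator Sampling and Horvitz-Thompson Estimation
    of Total Number in Sparse Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design-based stereology for sparse, inhomogeneously distributed
    cell populations. Implements the proportionator estimator: automated
    image-analysis weights per unbiased-frame tile, smooth (unimodal)
    arrangement of all tiles of the fractionator supersection, repeated
    independent systematic sampling with probability proportional to weight,
    Horvitz-Thompson estimation of total cell number with a direct tripartite
    coefficient-of-error, group statistics with PROBE design optimization
    diagnostics, and a classical uniform fractionator baseline for
    comparison. Includes a synthetic tissue simulator (clustered sparse cell
    populations, exhaustive sectioning into physical disector pairs, tile
    tessellation and stain-pixel weighting) and a Monte-Carlo benchmark of
    the two estimators, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
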