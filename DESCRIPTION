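Package: wmtract
Title: Virtual Dissection and Reproducibility Analysis of White-Matter Tractograms
Version: 0.1.0
Authors@R: person("wmtract", "developers", role = c("aut", "cre"),
    email = "wmtract@example.org")
Description: Automated virtual dissection of whole-brain diffusion MRI
    tractograms into named white-matter bundles using a declarative
    68-bundle protocol of inclusion and exclusion volumes of interest,
    together with the statistics needed to quantify test-retest
    reproducibility of the dissected bundles: streamline-density maps,
    weighted Dice similarity, Dice, density correlation, volume overlap
    and overreach, bundle adjacency, and single-measure absolute-agreement
    intraclass correlation.  Includes minimal readers and writers for the
    TCK, TRK and NIfTI-1 formats, a synthetic streamline-phantom generator
    for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
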