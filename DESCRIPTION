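Package: netmod
Title: Network Modification Treatments for Maladaptive Behavior in Model Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of small feedforward neural networks that
    drive a four-cue, four-action behavioral task and exhibit either
    aversion-resistant or aversion-sensitive alcohol drinking.  Provides
    systems-neuroscience characterization of the trained networks (node
    silencing, normalized mutual-information encoding with interaction
    correction, functional node relabeling via PCA and k-means,
    Kolmogorov-Smirnov population comparison), network "treatments" by
    retraining, ordered parameter imposition and derivative-free iterative
    Gaussian random search over single parameters and parameter pairs, and
    leave-one-out partial-least-squares prediction of effective parameter
    modifications from limited structural or activity information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
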