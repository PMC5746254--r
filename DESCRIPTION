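Package: plaidnet
Title: Recurrent Network Models of Grating and Plaid Responses in Mouse V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates linear-threshold rate networks of mouse primary visual
    cortex (V1) layer 2/3 under alternative rules for local recurrent excitatory
    connectivity (random Peters'-rule, like-to-like, feature-binding), and
    analyses the resulting grating and plaid responses. Includes a five-node
    analytical model with Jacobian stability classification (inhibition-
    stabilised network test, competition measurement, phase diagrams and
    stimulus-mixture experiments), generators for large-scale connectivity on a
    torus with orientation-tuned synapse probabilities, grating/plaid stimulus
    protocols and input currents, response metrics (orientation, plaid
    selectivity and modulation indices, pairwise signal correlations and their
    grating-vs-plaid R squared), a calcium-imaging-like trial variability model
    with responsivity filtering, a bootstrap component-response control, and
    synthetic ground-truth datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
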