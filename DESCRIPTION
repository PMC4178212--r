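Package: fluxcue
Title: Expression-Guided Prediction of Metabolic Flux Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates condition-specific gene expression into a stoichiometric
    metabolic network to predict which reactions carry flux. Gene expression is
    discretized into trinary cues (high / moderate / low), mapped to reactions
    through gene-protein-reaction rules, and reconciled with steady-state mass
    balance by an exact mixed-integer program that maximizes the number of
    satisfied cues (the iMAT approach). Reactions are classified as active,
    inactive or undetermined by forced-state re-optimization, predicted flux is
    compared across conditions by optimum-preserving flux variability, and
    pathway over-representation among active reactions is assessed with a
    one-sided hypergeometric test under Benjamini-Hochberg false discovery rate
    control. Includes readers for a documented JSON model dialect and an SBML
    Level 3 FBC subset, and a synthetic-data generator that plants a glucogenic
    pathway in a hepatocyte-like toy network for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
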