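Package: zincfold
Title: Zinc-Linked Folding Thermodynamics of the p53 DNA-Binding Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium analysis of zinc-coupled protein folding for the p53
    DNA-binding domain (DBD). Implements the four-state apo/holo x
    folded/unfolded linkage model, Gibbs-Helmholtz stability-curve
    extrapolation, two-state linear-extrapolation fitting of chemical
    denaturation melts with pooled m-values, zinc-linkage and stability-curve
    regression with prediction-interval outlier rejection, direct and
    competitive (FluoZin-3) zinc-binding analysis with the Munson-Rodbard
    IC50-to-Ki correction, global DNA-anisotropy fitting, chelator-buffered
    free-zinc speciation, temperature/zinc energy-landscape generation, and
    mechanistic classification of tumour mutants. Includes seeded synthetic
    generators for every assay type so the whole pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
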