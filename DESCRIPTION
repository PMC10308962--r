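Package: zc16S
Title: Carbon Oxidation State of Community Reference Proteomes Along Redox Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the oxidation-reduction potential (Eh) of microbial
    habitats to the average carbon oxidation state (Zc) of community
    reference proteomes estimated from 16S rRNA gene taxonomic
    classifications. Builds per-taxon reference proteomes from protein
    sequences, assembles abundance-weighted community amino acid
    compositions from RDP Classifier fixed-rank output, corrects field Eh
    measurements to pH 7 (Eh7) with the Nernst slope, computes
    metastable-equilibrium relative stability diagrams for proteomes on an
    Eh-pH grid, simulates incomplete equilibrium against random biological
    variation, and provides the regression and exact binomial sign-test
    machinery used to summarise Zc-Eh7 correlations across many datasets.
    Includes a synthetic survey generator so the whole pipeline can be
    exercised and validated without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
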