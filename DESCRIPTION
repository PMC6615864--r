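Package: dropscreen
Title: Pooled shRNA Dropout Screen Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled shRNA dropout screens for identifying
    G-quadruplex-ligand sensitiser genes: hairpin counting from barcode
    reads by exact or single-mismatch hash matching, counts-per-million
    abundance filtering, trimmed-mean-of-M-values (TMM) normalisation,
    negative-binomial dispersion estimation by Cox-Reid adjusted profile
    likelihood (common and tagwise with empirical-Bayes shrinkage),
    per-hairpin GLM likelihood-ratio tests for treatment-versus-baseline
    contrasts, Benjamini-Hochberg false discovery rates, gene-level
    sensitiser calling by hairpin-aggregation rules, cross-screen set
    logic, and gene-set enrichment (Fisher fold enrichment, right-sided
    hypergeometric tests, EASE scores). Includes a generative simulator
    of pooled screens with known ground truth (selection during passaging,
    representation bottlenecks, negative-binomial sequencing noise) plus
    pharmacology models: four-parameter logistic dose-response with GI
    extraction, Bliss-independence synergy surfaces, and one-site
    saturation binding fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea
Config/testthat/edition: 3
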