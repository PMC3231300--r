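Package: odorhedonics
Title: Hedonic Valence of Odorants from Odor Profiles and Molecular Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-odor relationship (QSOR) toolkit for
    estimating the pleasantness (hedonic valence) of odorants. Implements
    descriptor-weighted hedonic scoring of numerical odor-character profiles
    against a hedonic-tone vocabulary, extraction of a candidate hedonic
    dimension from profile matrices by principal component analysis with
    cross-validated Q2 component retention, molecular featurization from
    SMILES or molecular formulas (heavy-atom count and oxygen, sulfur,
    carboxylic-acid and amine indicators), ordinary least-squares models
    relating hedonic scores to those features with regression diagnostics,
    a registry of published prediction equations with their analytic
    properties (pleasantness thresholds and hedonic optima in molecular
    size), and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
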