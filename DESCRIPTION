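Package: phyllodisturb
Title: Fungicide Disturbance and Resilience Analysis for Crop Phyllosphere Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing fungicide disturbance and
    resilience of paired fungal/prokaryote amplicon (OTU) communities in a
    factorial field design: abundance/occupancy pre-filtering, Bray-Curtis
    ordination with PERMANOVA, multivariate-dispersion and partial constrained
    analysis of principal coordinates (CAP) permutation tests, ANCOM
    differential abundance with the W statistic, classification of taxon
    recovery dynamics (recovered, non-recovered, locally extinct, indirect),
    abundance-occupancy core-microbiome detection, Meinshausen-Buhlmann
    co-occurrence meta-networks with StARS regularization selection and
    per-sample subnetwork complexity, and random-forest linkage of prokaryote
    abundance to fungal-group richness with Boruta-style feature selection.
    Includes a synthetic-data generator that emulates the factorial field
    design with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    permute,
    randomForest,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
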