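Package: micromet
Title: Modelling Microbiome-Metabolome Relationships with Multivariate
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts community metabolome profiles from microbiome
    abundance features using a multivariate feedforward neural network,
    identifies significantly well-predicted metabolites against a
    shuffled-data background distribution, derives signed
    microbe-to-metabolite attribution scores from the learned network
    weights (Olden's connection-weight method), and organizes microbes
    and metabolites into interacting modules by consensus biclustering
    of the attribution matrices. Includes compositional transformations
    (relative abundance, centered log-ratio), iterated k-fold
    cross-validation with nested random hyperparameter search, a
    synthetic paired-data generator with planted module structure, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
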