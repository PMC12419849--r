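Package: gaclock
Title: Multi-Tissue Epigenetic Clocks via a Penalised Genetic Algorithm
    Islands Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-methylation age predictors ("epigenetic clocks")
    for collections of tissues with unbalanced age distributions. CpGs are
    selected by a penalised genetic algorithm islands model whose ridge
    regression fitness equally weights cross-validated error in every
    tissue and charges 0.01 years per included CpG; the final clock is an
    elastic net on principal components of the selected CpGs' M-values
    against log-linear transformed age. Includes a random-CpG baseline
    model, power and sample-size machinery for age-acceleration
    experiments, evaluation statistics (per-tissue errors, technical
    replicate concordance, population-doubling regression, group
    acceleration contrasts), and a synthetic multi-tissue methylation
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
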