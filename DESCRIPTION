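Package: thermadapt
Title: Thermal Selection Experiment Analysis for Pooled Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing long-term thermal selection
    experiments in clonal microbial populations (for example marine diatoms).
    Provides thermal performance curve fitting with a modified
    Sharpe-Schoolfield model and closed-form optimum temperature,
    photosynthesis-irradiance (photoinhibition) curve fitting and carbon-use
    efficiency budgets, a pooled-resequencing variant filtering and
    fixation-calling framework based on a binomial allele-frequency model,
    molecular divergence statistics (AMOVA with permutation tests, PERMANOVA,
    dispersion homogeneity, PCA with loading-treatment association, and
    score-weighted Kolmogorov-Smirnov enrichment), and a synthetic-data
    generator that emulates every input the pipeline consumes with known
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
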