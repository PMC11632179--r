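Package: gemeval
Title: Genetic Evaluation of Multivariate Traits and Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates multivariate quantitative traits, such as machine
    learning derived embeddings, for their utility in genetic discovery along
    two axes. Heritability is measured by combining per-component univariate
    genome-wide association Wald statistics into a chi-square test, clumping
    by linkage disequilibrium, and counting independent genome-wide
    significant loci together with their mean and median chi-square.
    Disease relevance is measured by building per-component polygenic scores
    on a discovery cohort and testing, on a held-out evaluation cohort,
    whether they improve prediction of a disease label over covariates alone
    using a permutation-plus-bootstrap model-comparison test. Includes an
    infinitesimal-model simulator of genotypes, embedding components, and a
    disease liability for validating that the two axes are disentangled, and
    readers and writers for PLINK 1 binary genotypes and tab-separated
    summary-statistic, weight, and score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
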