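Package: sexconflictr
Title: Genomic Signatures of Intralocus Sexual Conflict from Expression
    and Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting genomic signatures of
    intralocus sexual conflict from RNA-seq derived data across species.
    Estimates site frequency spectra, Tajima's D and intersexual Hudson's
    F_ST directly from genotype likelihoods; classifies tissue-biased and
    sex-biased genes from TMM-normalized expression; contrasts balancing
    selection across gene classes with Wilcoxon, covariate-regression,
    polynomial and permutation approaches; and relates per-species relative
    Tajima's D to sexual-dimorphism proxies with phylogenetic generalized
    least squares under Pagel's lambda. Ships a synthetic-data generator
    that emulates the statistical structure of the real inputs so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
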