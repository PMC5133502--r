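Package: famcombine
Title: Combining Family-Based Rare-Variant Association Tests by Kinship-Aware Permutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A permutation framework for combining multiple family-based,
    gene-based rare-variant tests of association into a single summary
    p-value. Fits a linear mixed model with a pedigree-derived
    kinship-proportional polygenic random effect, whitens the phenotype
    residuals so they are exchangeable across related individuals, and
    permutes them to calibrate eight weighted score-statistic tests (burden
    and variance-component forms at powers one to four, under Wu-style
    Beta(1,25) and Price-style 1/sqrt(p(1-p)) variant weights) together with
    their min-p combination, which accounts for the correlation between
    tests. Includes a pedigree simulator with gene-dropped genotypes and
    polygenic quantitative traits for type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
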