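Package: beeQMP
Title: Quantitative Microbiome Profiling of the Honeybee Gut
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Absolute quantification of honeybee gut bacteria from qPCR
    assays and 16S rRNA gene amplicon counts. Fits qPCR standard curves
    with explicit limit-of-detection semantics, converts quantification
    cycles to actin-normalized copy numbers and genome equivalents,
    scales amplicon proportions to absolute per-phylotype abundances
    using a universal 16S load (quantitative microbiome profiling),
    and provides the permutation-based inference used for such data:
    permutation ANOVA and t-tests, PERMANOVA on Bray-Curtis
    dissimilarities, multivariate dispersion tests, and PCA with a
    zero-to-one log rule. A synthetic-data generator emulates the
    forager/nurse/winter-bee community structure so the whole pipeline
    can be exercised and tested without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
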