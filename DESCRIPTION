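Package: sipresponse
Title: Cross-Dataset Classification of Pheromone-Responsive Genes from
    RNA-seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative differential-expression workflow for comparing the
    transcriptomic response to a sex-inducing pheromone between the two
    mating types of a diatom, each profiled in an independent RNA-seq
    time-course dataset. Genes are tested per time point with negative
    binomial generalized linear models against a fold-change threshold
    (TREAT-style Wald tests) and, symmetrically, for equivalence (TOST)
    within the same fold-change margin; per-dataset decisions are made with
    a two-stage screening/confirmation procedure controlling the gene-level
    overall false discovery rate, and then combined across datasets to
    classify genes as responsive in both mating types (SRB), in mating
    type plus only (SRP), or in mating type minus only (SRM). Includes a
    negative binomial count simulator with planted gene classes for
    calibration and benchmarking, hypergeometric term enrichment, and
    leading-log-fold-change multidimensional scaling summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
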