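Package: licur
Title: Person-Oriented Longitudinal Pattern Analysis with LICUR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-oriented analysis of longitudinal panels of z-scored
    operating factors: preprocessing of raw multi-attempt measures into
    factor profiles, diagnosis of missingness (Little's MCAR test) and
    single imputation by a multivariate-normal EM algorithm, residue
    screening (LICUR step 1), per-timepoint Ward clustering with the
    Mojena stopping rule and k-means relocation (step 2), structural
    stability matching of cluster centroids and exact hypergeometric
    testing of developmental types and antitypes with odds ratios
    (step 3), plus a synthetic panel generator with ground truth for
    recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
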