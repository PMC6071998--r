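Package: girscan
Title: Population Structure and Selection-Signature Scans for Diverged
    Cattle Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genetic differentiation between two recently
    diverged livestock populations from SNP-array data: genotype and marker
    quality control, principal component analysis with K-means/BIC cluster
    inference and discriminant axes (DAPC-style), per-locus Nei diversity
    statistics (Ho, Hs, Ht, Fis, Fst) with control-chart outlier detection,
    within-population iHS and cross-population XP-EHH haplotype scans with
    frequency-bin standardisation and -log10 p transforms, candidate-window
    construction with gene/QTL overlap, and a forward Wright-Fisher simulator
    of two populations splitting under divergent selection for end-to-end
    validation. Results are returned as tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    MASS,
    vcfR,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
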