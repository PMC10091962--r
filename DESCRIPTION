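Package: hybridspace
Title: Phenotypic Variation and Transgressive Segregation in Hybrid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies phenotypic variation and transgressive segregation in
    interspecific hybrid crosses. Builds multivariate trait spaces from raw
    brain morphometrics (ellipsoid region volumes, log-scale allometric
    residuals) and from trials-to-criterion learning scores, measures group
    phenotypic dispersion as the hypervolume of the 95% kernel density
    contour region (Gaussian product kernel, cross-validated grid-search
    bandwidth), classifies hybrid individuals as transgressive when they fall
    outside both parental 95% density regions, builds a simulated-hybrid null
    by midparent resampling of observed parental individuals, and locates
    hybrid group means relative to the inter-parental axis via parental-bias
    and phenotypic-mismatch geometry. Ships a synthetic-study generator with
    known ground truth so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
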