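Package: charpop
Title: Morphological and Population-Genomic Divergence Analysis for Lake-Dwelling Arctic Char
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess morphological and genetic divergence among
    lake populations of arctic char (Salvelinus alpinus) and similar
    polymorphic fishes. Implements allometric size adjustment of linear
    morphometric traits, model-based (Gaussian mixture) size-class
    detection with BIC selection, otolith back-calculation of length at
    age by the biological intercept method, SNP filtering from VCF input,
    pairwise-complete genotype covariance and principal components,
    Reich-Patterson F_ST with locus-bootstrap confidence intervals,
    folded site-frequency spectra and Watterson's theta, heterozygosity
    and F_IS, the VanRaden/Endelman additive relationship matrix,
    sex-linked locus detection through discriminant analysis of principal
    components, maximum-likelihood admixture and stock-mixture clustering
    with cross-validated choice of K, and PERMANOVA model search over
    lake-level ecological predictors. A synthetic-study generator with
    planted truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mclust,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    vegan,
    permute
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
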