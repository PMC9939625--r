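Package: ssrfp
Title: SSR Fingerprint Databases for Plant Variety Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exploiting SSR (microsatellite)
    fingerprint databases in plant variety identification and distinctness
    (DUS) screening. Covers codominant genotype I/O with reference-based
    allele calibration, per-locus diversity statistics (major allele
    frequency, allele counts, observed and expected heterozygosity,
    polymorphic information content, Fst), Nei (1972) genetic distance and
    UPGMA clustering, pairwise discrimination assessment with
    undistinguished-group detection, greedy core-marker selection and
    multiplex fluorescent panel design, model-based admixture inference
    with Evanno delta-K model choice, AMOVA, genotype PCA, and integration
    of coded morphological characteristics via simple-matching similarity
    and Mantel tests. A seeded F-model simulator generates genotype and
    trait data with realistic population structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
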