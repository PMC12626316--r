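Package: teadiv
Title: Phenotypic and SSR Marker Diversity Analysis for Tea Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint phenotypic and microsatellite (SSR) genetic diversity
    analysis for germplasm collections, built around a survey of 40 wild tea
    accessions from seven populations in Chongzuo, Guangxi. Implements
    Shannon-Weaver trait diversity and coefficients of variation, grading of
    quantitative traits, codominant marker statistics (Na, Ne, I, Ho, He, F,
    PIC), three-level AMOVA with pairwise Fst and island-model gene flow,
    Nei (1972) genetic distance, UPGMA dendrograms with Newick export, Mantel
    matrix-correlation tests, and a Gibbs-sampling admixture model with
    Evanno delta-K cluster-number selection. Includes a Balding-Nichols
    synthetic-data generator so every stage is testable end to end, and
    bundles the survey's published summary tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
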