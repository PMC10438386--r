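Package: landgea
Title: Landscape Genomics: Gene-Environment Association, Allelic Turnover
    and Genomic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for range-wide adaptation analysis in
    non-model species: SNP filtering and LD pruning of diploid dosage
    matrices, sparse nonnegative matrix factorization of ancestry with
    cross-entropy model choice, latent-factor gene-environment association
    with genomic-inflation calibration and Benjamini-Hochberg correction,
    gradient-forest allelic-turnover modelling on environmental and PCNM
    spatial predictors, projection of turnover over raster grids, genomic
    offset under future climate scenarios, and seed-source genomic
    similarity mapping for assisted migration.  Includes a synthetic-data
    generator with known ground truth (admixed populations, environmental
    clines, correlated rasters, shifted future climates) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger
Config/testthat/edition: 3
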