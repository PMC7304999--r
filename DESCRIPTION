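Package: canopyfly
Title: Butterfly Community Analysis Along Canopy-Cover Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how butterfly (or other transect-surveyed
    insect) communities respond to a grassland-savanna-forest canopy-cover
    gradient. Converts line-transect counts to densities by half-normal
    distance sampling with taxonomic pooling of sparse species and
    apportionment of records identified only to higher taxa; computes
    per-survey and per-site community metrics (richness, total density,
    a NatureServe-rank-weighted conservation value index, ACE richness,
    species accumulation curves); runs composition analytics
    (one-dimensional principal-curve ordination, Dufrene-Legendre indicator
    values with permutation tests, predictive co-correspondence analysis)
    and permutation or rank-based inference (PERMANOVA with pairwise
    comparisons, Kruskal-Wallis with Dunn's test, Spearman correlation,
    Benjamini-Hochberg adjustment); locates canopy-cover response peaks by
    cubic or Gaussian-peak regression; and ships a synthetic transect-survey
    generator with full ground truth for estimator-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
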