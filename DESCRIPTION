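Package: petalmorph
Title: Landmark Geometric Morphometrics of Floral Symmetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based geometric morphometrics for quantifying corolla
    symmetry in pentamerous flowers, built around the five petal-apex
    landmark scheme used for Core Goodeniaceae (fan, bilabiate and
    pseudo-radial corollas). Provides generalized Procrustes
    superimposition, bilateral object-symmetry decomposition into
    symmetric and asymmetric shape components, Procrustes ANOVA,
    principal component analysis of symmetric shape with landmark
    reconstruction and morph interpolation, k-means morphotype
    clustering with species-level summaries, classical group statistics
    (Wilcoxon, Bartlett, Levene, one-way ANOVA, linear regression), a
    TPS/delimited-table landmark reader, and a synthetic pentamerous
    flower generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    car,
    jsonlite,
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
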