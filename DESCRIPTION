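Package: quadmorph
Title: Phylogenetic Geometric Morphometrics of the Avian Quadrate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics and phylogenetic
    comparative methods for densely landmarked skeletal elements such as
    the avian quadrate. Provides curve resampling, generalized Procrustes
    analysis with minimum-bending-energy sliding of curve and surface
    semi-landmarks, shape principal components with thin-plate-spline
    warp prediction, Pagel's lambda estimation on multivariate residuals,
    lambda-rescaled phylogenetic generalized least squares with residual
    randomization (RRPP) significance, phylogenetic two-block partial
    least squares for evolutionary integration, principal coordinates
    analysis of semi-quantitative diet profiles, landmark-scheme
    validation via Mantel tests, and a synthetic shape-evolution
    generator for end-to-end verification at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    vegan,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
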