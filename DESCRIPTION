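Package: rotormap
Title: Optical-Mapping Analysis of Re-Entry Cores in Cardiomyocyte Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing calcium- and voltage-sensitive fluorescence
    recordings of cardiomyocyte monolayers that exhibit focal triggers and
    re-entrant (rotational) activity. Builds per-cycle activation maps from
    the point of steepest fluorescence upstroke, counts and classifies
    wavefronts, localizes trigger sites, detects conduction-block cores from
    circular activation-time delays between neighbouring pixels, classifies
    core morphology (single line, lines plus area, multiple lines) and
    measures core perimeter by convex-hull fitting. Includes a ground-truthed
    synthetic-monolayer generator (excitable cell lattice plus analytic rotor,
    planar-wave and focal phantoms with dual voltage/calcium channels), the
    study-level statistics (Fisher's exact test with Bonferroni correction,
    Mann-Whitney with Dunn adjustment, Kolmogorov-Smirnov normality, linear
    regression) and end-to-end synthetic experiments for colony-size and
    spatial-stability questions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    EBImage,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
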