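Package: nucleomech
Title: Nuclear Morphometry, Envelope Permeability and Lamina Mechanics from Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of nuclear mechanotransduction in cultured
    cells: extraction of nuclear contours and spline-based curvature profiles,
    ellipsoidal nuclear shape models with meridian/parallel curvature
    decomposition, single-molecule tracking with nuclear-envelope crossing
    statistics, fluorescence intensity morphometry (coefficient of variation,
    edge-to-interior ratios, two-segment lamin rim profiles, actin
    directionality, local correlation maps), and Kelvin-Voigt viscoelastic
    fitting of constant-force creep curves. Includes a synthetic-data
    generator producing images, movies and traces with known ground truth so
    that every estimator can be validated end to end, plus non-parametric
    cohort statistics and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
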