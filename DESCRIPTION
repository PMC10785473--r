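Package: ductresist
Title: Hydraulic Resistance of Nonuniform Ducts and Perivascular Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for the hydraulic resistance per unit length of long,
    narrow ducts such as pial perivascular spaces, given their cross-sectional
    geometry along a centerline. Provides exact polygon metrics (area,
    perimeter, second moments, matched-ellipse aspect ratio), a per-section
    Poisson solver for the series-unidirectional resistance (SUN), the
    analytic circular solution (SUA), four fast closed-form approximations
    (area scaling, shape factor, matched ellipse, polar moment), classical and
    extended lubrication theory for nonuniform elliptical ducts, a correction
    factor driven by the second derivative of the area profile, an
    axisymmetric Stokes solver serving as ground truth for circular ducts,
    and parametric generators of synthetic duct geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
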