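Package: rbcgeom
Title: Erythrocyte Geometry from Diameter and Mean Corpuscular Volume
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form geometric models of the mammalian erythrocyte
    (sphere, cylinder, biconcave oblate spheroid with concave caps, and
    elliptical cylinder for camelids), with a four-step protocol that
    estimates cell thickness and membrane surface area from just the mean
    diameter and the mean corpuscular volume (MCV). Includes the validity
    screen for the biconcave model (central pallor, thickness-to-diameter
    ratio, eccentricity domain), model-comparison machinery based on the
    mean absolute percentage error (MAPE), packaged comparative hematology
    tables, CSV batch processing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
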