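Package: pholiage
Title: Light Capture and Photosynthesis of Individual Tree Crowns in
    Vegetation Stands with Liberation Gaps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional canopy model of instantaneous whole-crown
    light capture and net photosynthesis for an individual tree with an
    ellipsoidal crown embedded in a homogeneous vegetation stand treated as
    a turbid medium. A cylindrical "liberation" gap of variable radius can
    be cleared around the stem, emulating the silvicultural practice of
    releasing young target trees from light competition. Light is traced
    from a discretized overcast sky through the vegetation and the crown
    using Beer-Lambert extinction with leaf-angle projection functions;
    leaf nitrogen, photosynthetic capacity and a non-rectangular hyperbola
    light response convert absorbed light into carbon gain. Includes
    simulation experiments over gap radius, stand leaf area index, stand
    height and successional stands, packaged species and stand parameter
    fixtures, a seeded synthetic-scene generator, and YAML/JSON
    configuration support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
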