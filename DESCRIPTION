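Package: glyphscape
Title: Multilevel Data Glyphs for Visual Exploration of Biomedical Record Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements multilevel (semantic-zoom) data glyphs for the visual
    exploration of large tabular biomedical record sets such as cancer
    registries. Provides the 16-slot cubic glyph specification with three
    levels of detail (pixel, iconic, detail), automatic traffic-light
    validation of data-variable to visual-variable mappings based on
    measurement scale and channel length, dimetric-grid glyph placement
    (age pyramids, grouped small multiples, discretized scatter) with
    painter-ordered deterministic SVG and PNG rendering, conjunctive
    range filters with linked overall-versus-selected histogram panels,
    and a seeded synthetic cancer-registry generator for reproducible
    examples and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
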