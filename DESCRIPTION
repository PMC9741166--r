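Package: multirose
Title: Multidimensional and Stacked Rose Charts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Layout and rendering for multidimensional rose charts, a
    polar-area (Nightingale/coxcomb) generalisation for category-by-attribute
    tables. Partitions the circle into equal-angle petals, encodes values by
    radius or annular area, stacks attributes as radial layers, shades each
    petal's colour by value magnitude, annotates per-attribute extremes, and
    emits deterministic standalone SVG plus a renderer-independent JSON chart
    model. Includes a command-line interface and a synthetic table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    farver,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
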