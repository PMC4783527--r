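Package: synviz
Title: Vector and Raster Visualization of Genome Synteny and Collinearity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts genome synteny and collinearity results in the
    MCScanX dialect (collinearity files plus gene-position annotations,
    either the simplified four-column format or GFF3) into publication
    figures: circular ideograms with ribbon chords, bar plots, macrosynteny
    dot plots, and dual-synteny plots.  A backend-neutral scene graph is
    serialized to three vector formats (SVG, EPS, PDF) with byte-level
    deterministic output and rasterized to three pixel formats (PNG, JPEG,
    BMP).  Includes a seeded generator of format-valid synthetic fixtures
    and a command-line driver that renders any combination of the four plot
    types and six file formats in one call.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, graphics, stats, tools, utils
Suggests: testthat (>= 3.0.0), png, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
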