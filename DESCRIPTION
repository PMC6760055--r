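Package: ntsqbd
Title: Quality-by-Design Screening, Design Space and Material Grading for
    Notoginseng Total Saponin Manufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a quality-by-design (QbD) analysis of notoginseng total
    saponin (NTS) manufacturing. Computes extractable-content material quality
    attributes and eluate process quality attributes (saponin purities, total
    saponin purity, dry matter and total saponin yields), validates 10-factor
    definitive screening designs with coded/uncoded factor conversion,
    identifies critical process parameters and critical material attributes by
    p-value based bidirectional stepwise regression, computes a Monte Carlo
    probability-based design space over the critical process parameters, and
    grades raw-material batches by linear acceptance inequalities under either
    variable or fixed manufacturing parameters. Ships the 32-run screening
    study dataset the methods were developed on, and a synthetic-data
    generator emulating its statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
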