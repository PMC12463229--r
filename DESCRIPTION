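Package: ekhom
Title: Evolutionary Khovanov Homology for Knot Data Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar link diagrams from codes or from three-dimensional
    curves (such as nucleic-acid backbones), Kauffman bracket and Jones
    polynomials, Khovanov homology over the rationals, prime fields and
    the integers, and evolutionary Khovanov homology: distance-based and
    unzipping smoothing filtrations of a link diagram are turned into a
    tower of Khovanov complexes whose persistence module is decomposed
    into barcodes with per-stage degree profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse, ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
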