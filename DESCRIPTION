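Package: bivalvechron
Title: Growth-Increment Chronologies and Climate-Growth Analysis for Bivalves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and quality control of annually resolved
    growth-increment chronologies from bivalve shells, in the tradition of
    dendrochronology tooling (COFECHA-style crossdating verification,
    smoothing-spline and negative-exponential detrending, Tukey biweight
    chronology averaging, expressed population signal), together with the
    climate-growth inference stage used in sclerochronology: harmonic
    deseasonalization of monthly environmental series, growth-year alignment
    (October-September), Spearman correlation tables, and forward stepwise
    regression with AR(1) prewhitening. Includes a synthetic-data module that
    generates shell populations with known signal structure so the whole
    pipeline can be exercised and validated without field data, and
    reader/writers for the Tucson (RWL) decadal ring-width format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
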