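Package: otochron
Title: Otolith Growth-Increment Biochronologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses growth-increment biochronologies from fish
    otoliths using dendrochronology techniques. Detrends multi-transect
    increment-width series with cubic smoothing splines parameterised by a
    50% frequency cutoff, performs COFECHA-style crossdating quality control
    with lagged segment correlations, combines individual mean series into a
    mean index chronology with signal-strength statistics (interseries
    correlation, expressed population signal, mean sensitivity), applies an
    autoregressive (ARSTAN-style) standardization, and correlates the
    chronology against current- and previous-year environmental series.
    Includes readers and writers for Tucson RWL ring-width files and
    long-format increment tables, and a synthetic-data generator that
    emulates the sampling design of a weak-common-signal otolith study for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
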