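Package: paleolimr
Title: Chronology, Proxy Quantification, Zonation and Climate Metrics for
    Lake-Sediment Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for recent lake-sediment palaeolimnology:
    constant-rate-of-supply (CRS) 210Pb chronologies with 137Cs bomb-peak
    and post-bomb radiocarbon tie points and a quadratic age-depth model;
    exotic-marker (spike) microfossil concentrations, relative abundances
    and loss-on-ignition organic content; significance-tested
    stratigraphic zonation by optimal splitting on information content
    with a broken-stick null; and climate-linkage metrics from daily
    series (sea-ice phenology, stacked-station temperature
    reconstruction, melting-season length, decadal trends). Includes
    synthetic-data generators with known ground truth for every input
    class, and a configurable end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
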