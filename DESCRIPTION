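Package: biocharGHG
Title: Greenhouse Gas Inventory Accounting for Biochar Soil Amendments
Version: 1.0.0
Authors@R:
    person("Biochar GHG", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Emission-factor (IPCC tier-1 style) greenhouse-gas accounting for
    biochar additions to mineral soils. Estimates the organic carbon fraction
    of biochar from feedstock class and pyrolysis conditions, computes the
    fraction of that carbon persisting in soil over a chosen timeframe and
    mean annual soil temperature using multi-pool exponential decay with a
    temperature-dependent Q10 rate adjustment, adds an optional first-year
    nitrous oxide credit, and reports net avoided greenhouse-gas emissions in
    CO2-equivalents. Ships the underlying parameter tables with provenance, a
    decay-curve fitting engine for incubation time series, a synthetic-series
    generator, batch processing of activity data, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
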