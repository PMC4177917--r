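Package: wbepi
Title: Wastewater-Based Epidemiology of Pharmaceutical Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wastewater-based epidemiology: convert pharmaceutical
    concentrations measured in wastewater treatment plant influent, effluent
    and receiving rivers into daily mass loads, removal efficiencies and
    per-capita usage; forward-predict influent concentrations from
    prescription statistics; back-estimate the number of active drug users
    and antiviral compliance; and compare pandemic with non-pandemic periods.
    Includes a synthetic-data generator that reproduces the statistical
    structure of 24-h composite WWTP sampling (diurnal flow, discrete flush
    pulses, left-censoring at the limit of quantification, in-plant removal
    and river dilution) so every stage of the pipeline can be exercised and
    validated against known simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
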