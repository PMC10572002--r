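Package: bovitherm
Title: Mechanistic Heat and Mass Balance Simulation of Dairy Cattle
    Thermal Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A steady-state biophysical simulator for dairy cattle. Hourly
    sun and shade microclimates are derived from monthly site climate and
    solar geometry, and feed a coupled heat and mass balance model of a
    multi-part cow (porous haircoat, distributed internal heat generation,
    convective, radiative, conductive and evaporative exchange). A
    behavioural and physiological thermoregulation cascade finds the
    achievable milk production under heat stress, and lactation-curve,
    diet and water-balance accounting convert the energy solution into
    feed and drinking-water needs. Scenario drivers cover metabolic
    chamber sweeps, site-year integrations with warming and shade
    options, and Yates full-factorial sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
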