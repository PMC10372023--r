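Package: ftgr
Title: On-Demand Irradiation Scheduling from Tumor Growth Rate Fluctuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for growth-rate-guided scheduling of booster irradiations in
    preclinical photothermal tumor-vaccine studies. Converts longitudinal
    caliper measurements to tumor volumes, computes the fluctuation of tumor
    growth rate (FTGR) indicator and tumor growth inhibition (TGI), turns FTGR
    traces into on-demand boost decisions, estimates photothermal conversion
    efficiency from heating-cooling temperature traces by the single-compartment
    energy-balance method, and simulates synthetic cohorts (Gompertz growth with
    transient treatment-induced kill) and Newtonian thermal traces so the whole
    pipeline can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
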