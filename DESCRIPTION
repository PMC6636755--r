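Package: tremorcma
Title: Cost-Minimisation Modelling of MRgFUS Versus Unilateral DBS for
    Essential Tremor in Japan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-minimisation model comparing magnetic
    resonance-guided focussed ultrasound (MRgFUS) with unilateral deep brain
    stimulation (DBS) for medication-refractory essential tremor from a
    Japanese payer perspective. Provides tariff catalog handling (FFS, DPC and
    drug-tariff pricing with day-indexed hospitalisation fee schedules),
    staged direct-cost accounting with probability-weighted downstream
    procedures (radiofrequency thalamotomy re-treatment, electrode
    extraction), JHIFS hourly labour add-on scenarios with a day-of-procedure
    correction factor, one-way deterministic sensitivity analyses, and a
    seed-reproducible Monte Carlo probabilistic sensitivity analysis with
    moment-matched gamma and beta sampling. Includes a calibrated input set
    reconstructed from published aggregate costs via a linear-consistency
    oracle, and a seeded synthetic catalog generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
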