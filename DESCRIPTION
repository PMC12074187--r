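Package: cvrarima
Title: Multi-Resolution ARIMA Characterization of Cerebral Physiologic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the autocorrelative structure of continuously
    monitored cerebral physiologic signals across temporal resolutions. Derives
    cerebrovascular reactivity indices (PRx, PAx, RAC, RAP, COx) from high-frequency
    arterial blood pressure, intracranial pressure and oximetry waveforms via
    10-second averaging and moving Pearson correlations; reduces minute-resolution
    series over a non-overlapping resolution ladder with a gap-interpolation rule;
    classifies stationarity with built-in ADF and KPSS tests; grid-searches
    ARIMA (p,d,q) orders by AIC, BIC and log-likelihood; compares best-model
    criteria across clinical subgroups with a normality-gated test ladder; and
    evaluates one-step-ahead forecasts by Pearson correlation and Bland-Altman
    limits of agreement. Includes a seeded synthetic-cohort generator with tunable
    autoregulation coupling so every stage can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
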