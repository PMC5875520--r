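Package: stacksource
Title: Air-Kerma Modelling and Replacement Scheduling for Stacked
    Radiotherapy Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the air-kerma strength at the focus of a cobalt-60
    teletherapy or Gamma Knife unit when decayed sources are kept in
    service by stacking them behind newer ones.  Provides closed-form
    corrections for exponential photon attenuation through front
    capsules and for the inverse-square effect of the increased
    source-focus distance, staged source-replacement schedules
    (push-back and pair-combining) with activity- and
    encapsulation-savings accounting, and an independent
    forced-detection Monte Carlo estimator of the same relative
    air-kerma ratios for extended cylindrical sources.  Ships the
    Leksell 4C parameter set as a worked fixture together with a
    randomized scenario generator, a structured configuration format,
    and CSV/JSON report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
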