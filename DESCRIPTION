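Package: venticomp
Title: Breath-by-Breath Comparison of Simulated and Real Newborn
    Positive-Pressure Ventilation
Version: 0.1.0
Authors@R:
    person("J.", "Marsh", email = "jmarsh@example.org",
           role = c("aut", "cre"))
Description: Simulates T-piece positive-pressure ventilation (PPV) of a
    newborn manikin and of real newborns as pressure-flow waveforms, extracts
    per-inflation ventilatory parameters (peak inflating pressure, positive
    end-expiratory pressure, expired tidal volume, mask leak) the way a
    respiratory function monitor does, calls upper-airway obstruction, pairs
    simulated and clinical episodes by duration of PPV, and compares the four
    resulting groups longitudinally: median/IQR summaries, one-way
    random-effects panel models with Newey-West variance, LOESS trend curves,
    dynamical correlation with bootstrap confidence intervals, Pearson
    correlation and chi-square testing of obstruction occurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sandwich,
    withr,
    yaml
Config/testthat/edition: 3
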