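Package: sharkstress
Title: Simulation and Analysis of Temperature x pCO2 Multistressor
    Experiments on Neonatal Sharks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse 2x2 temperature by carbon dioxide
    partial pressure (pCO2) acclimation experiments on neonatal sharks. The
    package covers the full chain from raw measurements to effect estimates:
    seawater carbonate chemistry (open-cell Gran titration alkalinity and a
    CO2-system solver for pCO2 from NBS-scale pH, temperature, salinity and
    total alkalinity), intermittent-flow respirometry trait extraction
    (minimum oxygen uptake via the mean of the lowest normal distribution,
    maximum uptake from rolling 30-s slopes, aerobic scope, excess
    post-exercise oxygen consumption and recovery time), behavioural indices
    (detour-maze lateralisation, overall dynamic body acceleration, hypoxia
    tolerance), haematology (Drabkin's haemoglobin, haematocrit, MCHC),
    linear mixed-effects inference with simulation-based confidence
    intervals, and Monte-Carlo power analysis over replicate-group counts.
    A synthetic-data generator with known ground truth makes every stage
    testable by parameter recovery without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    MASS,
    mclust,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
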