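Package: lpfcflow
Title: Information Flow Across Lateral Prefrontal Multi-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for reversal-learning bandit sessions recorded
    on multi-electrode arrays in lateral prefrontal cortex. Implements
    Rescorla-Wagner behavioural modelling with asymmetric learning rates,
    sliding-window fixed-effect ANOVA encoding with response-latency
    detection, leave-one-trial-out linear Gaussian population decoding, and a
    Granger-style lagged regression that quantifies directed flow of decoded
    information between arrays (full vs. partial models, delta-posterior and
    fVar flow strengths, ordinal-distance and cross-domain summaries). A
    synthetic-session generator with planted tuning, latency gradients and
    lagged inter-array coupling makes every stage testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
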