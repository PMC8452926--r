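Package: ibbci
Title: Information-Bottleneck Classification Rules for SSVEP Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains classification rules for steady-state visual evoked
    potential (SSVEP) brain-computer interfaces by discretising
    class-conditional feature distributions (histogram or skew-normal fits),
    combining them under a conditional-independence model, and solving the
    generalized (deterministic) information bottleneck to obtain a classifier
    with a reject option. Includes mutual-information-based information
    transfer rate scoring, a sliding-window PSDA/CCA feature-extraction front
    end, a synthetic data generator, and cross-validation and parameter-scan
    utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
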