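Package: culsel
Title: Drift and Cultural-Selection Inference for Micro-Society Communication Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a mixed probabilistic model of communicative-variant choice
    (neutral drift, coordination bias, content bias and mutation) to coded
    micro-society communication-game data: 8 participants interacting in
    round-robin pairs over 7 generations, one variant production per
    participant per generation. Provides exhaustive maximum-likelihood grid
    fitting, best-account Bayes-factor model selection with bias
    classification, a forward simulator of micro-society corpora for
    parameter-recovery and calibration studies, and JSON/CSV corpus
    serialization with validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
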