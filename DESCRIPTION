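Package: noisylex
Title: Simulating Native and Non-Native Spoken-Word Recognition in Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating spoken-word recognition in background
    noise with a bilingual deep-autoencoder model.  Builds slot/feature
    phonological encodings and sparse binary semantics for synthetic
    bilingual lexicons, trains denoising autoencoders under asymmetric
    language exposure to emulate native and non-native listeners, and runs
    offline word-identification and online visual-world simulations
    together with an untrained input-matching baseline.  Includes
    mechanistic analyses of the network's activation states (rank-order
    competition measures, cumulative unique misperceptions,
    representational similarity analysis) and the statistical machinery for
    comparing model output with human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
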